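#' @import methods
#' @importFrom stats rnorm runif rbinom rmultinom pnorm median setNames
#' @importFrom utils write.table read.table head
#' @importFrom data.table data.table as.data.table rbindlist setorderv
NULL

# Per-stage RNG streams derived from one root seed, so each pipeline stage
# is reproducible in isolation. Offsets are arbitrary but fixed; the product
# is kept below 2^31 - 1.
.stageOffsets <- c(
  transcriptome = 101L, individuals = 211L, expression = 307L,
  reads_tame = 401L, reads_aggressive = 503L, saturation = 601L,
  nullsim = 701L
)

stageSeed <- function(seed, stage) {
  stopifnot(stage %in% names(.stageOffsets))
  as.integer((as.numeric(seed) * 7919 + .stageOffsets[[stage]]) %% 2147483587)
}

withStageSeed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stageSeed(seed, stage))
  expr
}

# Truncated normal by rejection; vectorised, exact for the modest
# truncation used by the read-length model.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

.assertProb <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  invisible(x)
}

.assertPositive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(what, " must be positive", call. = FALSE)
  invisible(x)
}

utils::globalVariables(c("anyNonRef", "allele", "refAllele", "base",
                         "insSeq", "count", "position", "depth"))
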