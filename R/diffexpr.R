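## Two-library read-count expression comparison: library-total
## normalization, fold change with direction, two-proportion Z statistic,
## two-sided p, DE screen, MA data, and the ddCt qPCR utility.

#' Normalize a read count by its library total
#'
#' @param x read count (vectorized).
#' @param N total reads in the same library.
#' @return the proportion x/N.
#' @examples
#' normalizeCounts(136, 2565892)
#' @export
normalizeCounts <- function(x, N) {
  if (any(N <= 0)) stop("library total must be positive", call. = FALSE)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  x / N
}

#' Fold change of normalized proportions, with direction
#'
#' Fold is the larger of the two library-normalized proportions over the
#' smaller, so it is always at least 1; direction labels which sample is
#' higher ("T>A", "A>T", or "tie"). When one proportion is zero the fold
#' is undefined under the default policy (NA, with the direction of the
#' non-zero side); the `pseudocount_1` policy instead recomputes with
#' both counts incremented by one.
#'
#' @param xT,xA read counts in the tame and aggressive libraries.
#' @param NT,NA_ the corresponding library totals.
#' @param policy zero-count policy, `"undefined"` or `"pseudocount_1"`.
#' @return data.frame with fold and direction (vectorized).
#' @examples
#' foldChange(136, 2565892, 402, 3379343)   # 2.24, A>T
#' @export
foldChange <- function(xT, NT, xA, NA_,
                       policy = c("undefined", "pseudocount_1")) {
  policy <- match.arg(policy)
  n <- max(length(xT), length(xA))
  xT <- rep_len(xT, n); xA <- rep_len(xA, n)
  pT <- normalizeCounts(xT, NT)
  pA <- normalizeCounts(xA, NA_)
  direction <- ifelse(pT > pA, "T>A", ifelse(pA > pT, "A>T", "tie"))
  direction[xT == 0 & xA == 0] <- "tie"
  fold <- ifelse(pmin(pT, pA) > 0,
                 pmax(pT, pA) / pmin(pT, pA), NA_real_)
  if (policy == "pseudocount_1") {
    zero <- pmin(xT, xA) == 0
    if (any(zero)) {
      pT2 <- normalizeCounts(xT[zero] + 1, NT)
      pA2 <- normalizeCounts(xA[zero] + 1, NA_)
      fold[zero] <- pmax(pT2, pA2) / pmin(pT2, pA2)
    }
  }
  data.frame(fold = fold, direction = direction,
             stringsAsFactors = FALSE)
}

#' Pooled two-proportion Z statistic for tag counts
#'
#' The default statistic is the pooled-variance two-proportion form
#' \deqn{\lambda = |p_T - p_A| / \sqrt{\bar p (1 - \bar p)
#'   (1/N_T + 1/N_A)}}
#' with \eqn{\bar p = (x_T + x_A)/(N_T + N_A)}. Both counts zero yields
#' NA. The statistic used by [deTable()] is pluggable, so an alternative
#' form can be swapped in without touching the screen.
#'
#' @param xT,xA read counts; `NT`, `NA_` library totals.
#' @return the statistic (vectorized, non-negative).
#' @export
zStatistic <- function(xT, NT, xA, NA_) {
  if (NT <= 0 || NA_ <= 0)
    stop("library totals must be positive", call. = FALSE)
  pT <- xT / NT
  pA <- xA / NA_
  pbar <- (xT + xA) / (NT + NA_)
  se <- sqrt(pbar * (1 - pbar) * (1 / NT + 1 / NA_))
  ifelse(xT + xA == 0, NA_real_, abs(pT - pA) / se)
}

#' Two-sided normal p-value
#'
#' Computes `p = 1 - |Phi(lambda) - Phi(-lambda)|`, the two-sided tail
#' probability `2 * (1 - Phi(|lambda|))` of the standard normal.
#'
#' @param lambda the Z statistic (vectorized; sign is irrelevant).
#' @return p in `[0, 1]`.
#' @examples
#' pTwoSided(1.959964)   # ~0.05
#' @export
pTwoSided <- function(lambda) {
  1 - abs(pnorm(lambda) - pnorm(-lambda))
}

#' Build the per-gene differential-expression table
#'
#' @param counts data.frame with columns gene, countT, countA.
#' @param NT,NA_ library totals; default to the column sums.
#' @param config a [ScreenConfig].
#' @param statistic the Z statistic function (signature as
#'   [zStatistic()]).
#' @return data.frame: gene, countT, countA, propT, propA, fold,
#'   direction, lambda, p, passesScreen — ordered by p ascending.
#' @export
deTable <- function(counts, NT = sum(counts$countT),
                    NA_ = sum(counts$countA),
                    config = ScreenConfig(), statistic = zStatistic) {
  stopifnot(is(config, "ScreenConfig"),
            all(c("gene", "countT", "countA") %in% names(counts)))
  fc <- foldChange(counts$countT, NT, counts$countA, NA_,
                   policy = config@zeroCountPolicy)
  lambda <- statistic(counts$countT, NT, counts$countA, NA_)
  p <- pTwoSided(lambda)
  out <- data.frame(gene = counts$gene, countT = counts$countT,
                    countA = counts$countA,
                    propT = normalizeCounts(counts$countT, NT),
                    propA = normalizeCounts(counts$countA, NA_),
                    fold = fc$fold, direction = fc$direction,
                    lambda = lambda, p = p,
                    stringsAsFactors = FALSE)
  out$passesScreen <- !is.na(out$fold) & out$fold >= config@minFold &
    !is.na(out$p) & out$p < config@maxP
  out[order(out$p), ]
}

#' Screen a differential-expression table
#'
#' A gene passes when its fold change is defined and at least `minFold`
#' and its two-sided p is below `maxP`.
#'
#' @param results output of [deTable()].
#' @param config a [ScreenConfig].
#' @return list with `table` (the flagged results) and `tally` (named
#'   counts of passers per direction: upTame = "T>A", upAggr = "A>T").
#' @export
deScreen <- function(results, config = ScreenConfig()) {
  stopifnot(is(config, "ScreenConfig"))
  pass <- !is.na(results$fold) & results$fold >= config@minFold &
    !is.na(results$p) & results$p < config@maxP
  results$passesScreen <- pass
  tally <- c(upTame = sum(pass & results$direction == "T>A"),
             upAggr = sum(pass & results$direction == "A>T"),
             total = sum(pass))
  list(table = results, tally = tally)
}

#' MA-plot data before and after library normalization
#'
#' M is the log2 tame/aggressive ratio, A the mean of the two log2
#' values; `pre` uses raw counts, `post` uses library-normalized
#' proportions. Zero counts take a pseudocount of 0.5 for the logs only.
#'
#' @param counts data.frame with gene, countT, countA.
#' @param NT,NA_ library totals.
#' @return list with `pre` and `post` data.frames (gene, A, M) and
#'   `medianM` (named vector of the two medians).
#' @export
maData <- function(counts, NT = sum(counts$countT),
                   NA_ = sum(counts$countA)) {
  xT <- ifelse(counts$countT == 0, 0.5, counts$countT)
  xA <- ifelse(counts$countA == 0, 0.5, counts$countA)
  pre <- data.frame(gene = counts$gene,
                    A = (log2(xT) + log2(xA)) / 2,
                    M = log2(xT) - log2(xA))
  post <- data.frame(gene = counts$gene,
                     A = (log2(xT / NT) + log2(xA / NA_)) / 2,
                     M = log2(xT / NT) - log2(xA / NA_))
  list(pre = pre, post = post,
       medianM = c(pre = median(pre$M), post = median(post$M)))
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes `2^-((CtTarget1 - CtRef1) - (CtTarget2 - CtRef2))`: the
#' expression of the target gene in sample 1 relative to sample 2, each
#' normalized to the endogenous reference gene.
#'
#' @param ctTarget1,ctRef1 threshold cycles of target and reference gene
#'   in sample 1.
#' @param ctTarget2,ctRef2 the same in sample 2.
#' @return the relative expression level.
#' @examples
#' ddCtRelativeExpression(20, 18, 22, 19)   # ddCt = -1 -> 2
#' @export
ddCtRelativeExpression <- function(ctTarget1, ctRef1, ctTarget2,
                                   ctRef2) {
  stopifnot(is.finite(ctTarget1), is.finite(ctRef1),
            is.finite(ctTarget2), is.finite(ctRef2))
  2^(-((ctTarget1 - ctRef1) - (ctTarget2 - ctRef2)))
}
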