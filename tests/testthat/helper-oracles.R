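# Independent oracles used across the suite. These deliberately use
# naive, direct algorithms (exhaustive DP, brute-force recounts,
# O(n*m) interval stabbing) so they share no code path with the package.

# Smith-Waterman with affine gaps (Gotoh), best local score only.
# Gap of length L costs gapOpen + L * gapExt, matching the package's
# alignment scoring convention.
oracleLocalScore <- function(pattern, subject, match = 2, mismatch = -3,
                             gapOpen = 5, gapExt = 2) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  n <- length(p); m <- length(s)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)      # match/mismatch state
  X <- matrix(NEG, n + 1, m + 1)    # gap in subject (pattern consumed)
  Y <- matrix(NEG, n + 1, m + 1)    # gap in pattern (subject consumed)
  bestScore <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (p[i - 1] == s[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + sub
      X[i, j] <- max(M[i - 1, j] - gapOpen - gapExt,
                     X[i - 1, j] - gapExt)
      Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExt,
                     Y[i, j - 1] - gapExt)
      bestScore <- max(bestScore, M[i, j])
    }
  }
  bestScore
}

# All exact placements of a read on a sequence (either strand),
# 1-based starts; brute force over every offset.
oracleExactPlacements <- function(read, seqChar) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  out <- list()
  for (strand_ in c("+", "-")) {
    q <- if (strand_ == "+") read else rc
    L <- nchar(seqChar); k <- nchar(q)
    if (k <= L) {
      for (st in seq_len(L - k + 1L)) {
        if (substring(seqChar, st, st + k - 1L) == q)
          out[[length(out) + 1L]] <- list(start = st, strand = strand_)
      }
    }
  }
  out
}

# Naive per-position recount of a pileup from known error-free read
# placements (origins with no indels): loops over reads and positions.
oracleRecount <- function(origins, haplotypes, readSeqs) {
  tab <- list()
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    hap <- as.character(haplotypes[[o$haplotype]][[o$gene]])
    for (off in seq_len(o$trueLength)) {
      pos0 <- o$start + off - 2L
      base <- substring(hap, o$start + off - 1L, o$start + off - 1L)
      key <- paste(o$gene, pos0, o$sample, base, sep = "\r")
      tab[[key]] <- (if (is.null(tab[[key]])) 0L else tab[[key]]) + 1L
    }
  }
  tab
}

# Naive interval stabbing with the same label priority, O(n*m).
oracleRegion <- function(chrom, pos0, annTable, knownChroms) {
  prio <- c(coding = 1, utr = 2, intron = 3, "repeat" = 4)
  vapply(seq_along(chrom), function(i) {
    if (!chrom[i] %in% knownChroms) return("unknown")
    hits <- annTable[annTable$gene == chrom[i] &
                       annTable$start <= pos0[i] + 1L &
                       annTable$end >= pos0[i] + 1L, , drop = FALSE]
    if (nrow(hits) == 0L) return("non-gene")
    lab <- hits$type[which.min(prio[hits$type])]
    c(coding = "coding", utr = "utr", intron = "intron",
      "repeat" = "repetitive")[[lab]]
  }, character(1))
}

# Hash-set dedup oracle for SNP-set merging.
oracleDedupKeys <- function(df) {
  unique(paste(df$chrom, df$chromPos, df$ref, df$alt, sep = "\r"))
}

# Independent re-statement of the tier rules, written as literal
# per-sample checks (used to cross-check the vectorized filter).
oracleTier <- function(refT, altT, refA, altA, minFrac = 0.25, m = 3L) {
  sampleOk25 <- function(r, a) {
    tot <- r + a
    if (tot == 0) return(TRUE)
    if (r > 0 && r / tot < minFrac - 1e-12) return(FALSE)
    if (a > 0 && a / tot < minFrac - 1e-12) return(FALSE)
    TRUE
  }
  rule25 <- sampleOk25(refT, altT) && sampleOk25(refA, altA)
  indAbove <- function(r, a) {
    if (r + a == 0) return(FALSE)
    (r == 0 || r > m) && (a == 0 || a > m)
  }
  indExact <- function(r, a) {
    if (r + a == 0) return(FALSE)
    (r == 0 || r == m) && (a == 0 || a == m)
  }
  if (rule25 && (indAbove(refT, altT) || indAbove(refA, altA)))
    return("A")
  if (rule25 && (indExact(refT, altT) || indExact(refA, altA)))
    return("B")
  if (min(refT + refA, altT + altA) >= m) return("C")
  "none"
}

# Small deterministic reference set used by several alignment tests.
makeToyRefs <- function(seed = 42, n = 3L, len = 400L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1))
  Biostrings::DNAStringSet(setNames(seqs, sprintf("gene%03d",
                                                  seq_len(n))))
}

mutateAt <- function(seqChar, pos, base) {
  substring(seqChar, pos, pos) <- base
  seqChar
}
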