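## Coverage breadth/depth, gene-yield saturation, divergence rates.

#' Breadth of coverage per reference transcript
#'
#' Breadth is the percent of a transcript's length covered by at least
#' one uniquely mapped read; only alignments flagged `isUnique`
#' contribute. Mean depth is computed over covered positions only.
#'
#' @param alignments data.frame from [alignReads()].
#' @param references the reference [Biostrings::DNAStringSet].
#' @return data.frame per reference: referenceId, length, coveredBases,
#'   breadth (percent), uniqueReadCount, meanDepth. The `meanBreadth`
#'   attribute holds the mean breadth over references with at least one
#'   unique hit.
#' @export
breadthOfCoverage <- function(alignments, references) {
  use <- alignments[alignments$isUnique %in% TRUE &
                      !is.na(alignments$refStart), , drop = FALSE]
  out <- data.frame(referenceId = names(references),
                    length = Biostrings::width(references),
                    coveredBases = 0L, breadth = 0,
                    uniqueReadCount = 0L, meanDepth = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    rows <- use[use$referenceId == out$referenceId[i], , drop = FALSE]
    out$uniqueReadCount[i] <- nrow(rows)
    if (!nrow(rows)) next
    ir <- IRanges::IRanges(rows$refStart + 1L, rows$refEnd)
    cov <- sum(IRanges::width(IRanges::reduce(ir)))
    out$coveredBases[i] <- cov
    out$breadth[i] <- 100 * cov / out$length[i]
    out$meanDepth[i] <- sum(IRanges::width(ir)) / cov
  }
  hit <- out$uniqueReadCount > 0
  attr(out, "meanBreadth") <- if (any(hit)) mean(out$breadth[hit]) else
    NA_real_
  out
}

#' Gene-yield saturation curve by nested subsampling
#'
#' Reads are subsampled without replacement in fixed-size units; nested
#' subsets (each dataset extends the previous) guarantee that the number
#' of genes detected (at least one mapped read) is non-decreasing in the
#' number of units.
#'
#' @param readGenes character vector: the gene each read mapped to (NA
#'   for reads that did not map).
#' @param unitSize reads per subsample unit.
#' @param geneUniverse declared gene universe for the percent scale.
#' @param seed seed for the subsampling permutation.
#' @param maxUnits cap on the number of units (default: all available).
#' @return data.frame: nUnits, nReads, genesDetected, genesDetectedPct.
#' @export
saturationCurve <- function(readGenes, unitSize, geneUniverse,
                            seed = 1L, maxUnits = NULL) {
  nReads <- length(readGenes)
  if (unitSize > nReads)
    stop("unitSize (", unitSize, ") exceeds available reads (", nReads,
         ")", call. = FALSE)
  nUnits <- nReads %/% unitSize
  if (!is.null(maxUnits)) nUnits <- min(nUnits, maxUnits)
  perm <- withStageSeed(seed, "saturation", sample.int(nReads))
  out <- data.frame(nUnits = seq_len(nUnits),
                    nReads = seq_len(nUnits) * unitSize,
                    genesDetected = 0L, genesDetectedPct = 0)
  seen <- character(0)
  for (k in seq_len(nUnits)) {
    ix <- perm[seq.int((k - 1L) * unitSize + 1L, k * unitSize)]
    seen <- union(seen, readGenes[ix][!is.na(readGenes[ix])])
    out$genesDetected[k] <- length(seen)
    out$genesDetectedPct[k] <- 100 * length(seen) /
      length(geneUniverse)
  }
  out
}

#' Per-base divergence summary
#'
#' Rates are reported as "one difference per N mapped bases", with N the
#' total mapped bases divided by each difference count, rounded to the
#' nearest integer. A zero count yields NA rather than an error.
#'
#' @param totalMappedBases total bases in read-reference contigs.
#' @param nFixed count of fixed (species-level) differences.
#' @param nPolymorphic count of within-species polymorphisms.
#' @param nExcluded differences excluded by the error floor.
#' @return list with the counts plus basesPerDifference, basesPerFixed,
#'   basesPerPolymorphism.
#' @examples
#' divergenceSummary(115987304, 898940, 88590)
#' @export
divergenceSummary <- function(totalMappedBases, nFixed, nPolymorphic,
                              nExcluded = 0L) {
  stopifnot(totalMappedBases > 0, nFixed >= 0, nPolymorphic >= 0)
  nTotal <- nFixed + nPolymorphic
  rate <- function(n) if (n > 0) as.integer(round(totalMappedBases / n))
    else NA_integer_
  list(totalMappedBases = totalMappedBases,
       nTotalDifferences = nTotal, nFixedDifferences = nFixed,
       nPolymorphisms = nPolymorphic, nExcluded = nExcluded,
       basesPerDifference = rate(nTotal), basesPerFixed = rate(nFixed),
       basesPerPolymorphism = rate(nPolymorphic))
}
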