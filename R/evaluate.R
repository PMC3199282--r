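## Calibration experiments: planted-truth SNP recovery, null
## false-positive rate of the expression screen, and fold recovery.

#' Measure SNP-caller recovery on a planted-truth simulation
#'
#' Runs the full simulate-map-call chain on a uniform-abundance
#' transcript set with SNVs planted at `snpRate`, then scores the
#' tier-A calls against the planted genotypes: sensitivity is the
#' fraction of planted sites recovered as retained tier-A SNVs with the
#' correct alternate allele; the false-discovery rate is the fraction of
#' tier-A calls at positions where nothing was planted.
#'
#' @param seed root seed for the simulation.
#' @param coveragePerSample target mean read depth per individual.
#' @param nGenes,geneLength reference set dimensions (bases).
#' @param snpRate planted variants per base (SNVs only).
#' @param thresholds a [MappingThresholds].
#' @param filterConfig a [SnpFilterConfig].
#' @param minSiteDepth pooled read depth a planted site must reach to
#'   enter the sensitivity denominator; the recovery guarantee is
#'   conditional on sites being sequenced to depth, and sites falling
#'   in the coverage ramps near transcript ends do not qualify.
#' @return list with sensitivity, fdr, nSites (planted sites at
#'   depth), nCalls (tier A), meanDepth (realized, pooled over
#'   samples).
#' @export
evaluateSnpRecovery <- function(seed = 1L, coveragePerSample = 25,
                                nGenes = 8L, geneLength = 2500,
                                snpRate = 0.01,
                                thresholds = MappingThresholds(),
                                filterConfig = SnpFilterConfig(),
                                minSiteDepth = 40) {
  nReads <- as.integer(round(
    nGenes * geneLength * coveragePerSample / 350))
  cfg <- SimConfig(nGenes = nGenes, geneLengthMean = geneLength,
                   geneLengthSd = 0, nReadsPerSample = nReads,
                   snpRate = snpRate,
                   variantClassMix = c(1, 0, 0),
                   deFraction = 0, abundanceLogSd = 0, seed = seed)
  sim <- simulateExperiment(cfg)
  aln <- rbind(
    alignReads(sim$reads$tame$reads, sim$references, thresholds,
               sample = "tame"),
    alignReads(sim$reads$aggressive$reads, sim$references, thresholds,
               sample = "aggressive"))
  pu <- buildPileup(aln, sim$references)
  recs <- classifyZygosity(
    filterHighConfidence(
      partitionDifferences(enumerateDifferences(pu), filterConfig),
      filterConfig),
    filterConfig)
  tierA <- recs[recs$retained & recs$tier == "A", , drop = FALSE]
  truth <- truthGenotypes(sim$truth)
  depth <- pileupDepth(pu)
  dt <- data.table::as.data.table(depth)
  siteDepth <- dt[, list(depth = sum(depth)),
                  by = c("referenceId", "position")]
  depthOf <- setNames(siteDepth$depth,
                      paste(siteDepth$referenceId, siteDepth$position))
  truthPosAll <- paste(truth$gene, truth$position - 1L)
  atDepth <- !is.na(depthOf[truthPosAll]) &
    depthOf[truthPosAll] >= minSiteDepth
  truthPos <- truthPosAll[atDepth]
  truthKey <- paste(truthPos, truth$alt[atDepth])
  callPos <- paste(tierA$referenceId, tierA$position)
  callKey <- paste(callPos, tierA$alt)
  sens <- if (length(truthKey)) mean(truthKey %in% callKey) else
    NA_real_
  fp <- sum(!callPos %in% truthPosAll)
  list(sensitivity = sens,
       fdr = fp / max(1L, nrow(tierA)),
       nSites = length(truthKey), nCalls = nrow(tierA),
       meanDepth = sum(pu$count) /
         max(1L, length(unique(paste(pu$referenceId, pu$position)))))
}

#' Null false-positive rate of the two-proportion screen
#'
#' Draws per-gene counts for both libraries from one shared proportion
#' (a binomial null with expected count `expected` per library) and
#' reports the fraction of genes with a two-sided p below `alpha`.
#'
#' @param nGenes number of null genes.
#' @param librarySize total reads per library.
#' @param expected expected read count per gene per library.
#' @param alpha significance threshold.
#' @param seed seed for the draws.
#' @return list with rate, nGenes, alpha.
#' @export
evaluateDeTypeI <- function(nGenes = 2000L, librarySize = 5e5,
                            expected = 50, alpha = 0.05, seed = 1L) {
  withStageSeed(seed, "nullsim", {
    p <- expected / librarySize
    xT <- rbinom(nGenes, librarySize, p)
    xA <- rbinom(nGenes, librarySize, p)
    lam <- zStatistic(xT, librarySize, xA, librarySize)
    pv <- pTwoSided(lam)
    list(rate = mean(pv < alpha, na.rm = TRUE), nGenes = nGenes,
         alpha = alpha)
  })
}

#' Fold-change recovery on simulated expression truth
#'
#' Simulates a two-library expression profile with a known fold applied
#' to a fraction of genes, draws multinomial read counts at depth
#' `librarySize`, and reports the median estimated fold over the truly
#' differentially expressed genes.
#'
#' @param nGenes genes in the profile.
#' @param librarySize reads per library.
#' @param deFold planted fold.
#' @param seed root seed.
#' @return list with medianFold, deFold, nDeGenes, minExpected (smallest
#'   expected per-gene count, for checking the depth condition).
#' @export
evaluateFoldRecovery <- function(nGenes = 300L, librarySize = 5e5,
                                 deFold = 2, seed = 1L) {
  cfg <- SimConfig(nGenes = nGenes, deFraction = 0.2, deFold = deFold,
                   abundanceLogSd = 0.5, seed = seed)
  ab <- simulateExpression(cfg)
  counts <- withStageSeed(seed, "nullsim", {
    data.frame(gene = ab$gene,
               countT = as.integer(rmultinom(1, librarySize,
                                             ab$propTame)),
               countA = as.integer(rmultinom(1, librarySize,
                                             ab$propAggr)))
  })
  fc <- foldChange(counts$countT, sum(counts$countT), counts$countA,
                   sum(counts$countA))
  de <- ab$isDE
  list(medianFold = median(fc$fold[de], na.rm = TRUE),
       deFold = deFold, nDeGenes = sum(de),
       minExpected = min(c(ab$propTame, ab$propAggr)) * librarySize)
}
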