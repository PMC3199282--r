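#' Simulation parameters for the two-library pyrosequencing emulator
#'
#' `SimConfig` holds every tunable of the synthetic-data generator: the
#' transcript set, the planted variant sites and their joint-zygosity mix,
#' the per-gene expression profile of the two libraries, and the 454-style
#' read model (truncated-normal read lengths, substitution errors,
#' homopolymer-scaled indels).
#'
#' Defaults reproduce the study conditions being emulated: read lengths
#' drawn from normal(376, 148) for the tame library and normal(358, 146)
#' for the aggressive library, truncated to \[50, 600\]; a joint-zygosity
#' mix proportional to the published 2x2 census of informative SNP classes;
#' substitution rate 0.001 and homopolymer indel coefficient 0.005 per
#' homopolymer unit.
#'
#' @param nGenes number of transcripts to simulate.
#' @param geneLengthMean,geneLengthSd transcript length model (bases).
#' @param nReadsPerSample reads generated per library.
#' @param readLengthMeanT,readLengthSdT tame-library read-length model.
#' @param readLengthMeanA,readLengthSdA aggressive-library read-length model.
#' @param readLengthMin,readLengthMax truncation bounds for read lengths.
#' @param subErrorRate per-base substitution error probability.
#' @param homopolymerIndelCoeff per-homopolymer-unit indel probability; a run
#'   of length r suffers an indel with probability
#'   `min(coeff * (r - 1), 0.1)`.
#' @param snpRate planted variants per reference base.
#' @param zygosityMix probabilities of the four joint zygosity classes, in
#'   the order hom-tame/hom-aggressive, het-tame/hom-aggressive,
#'   hom-tame/het-aggressive, het-tame/het-aggressive.
#' @param variantClassMix probabilities of the planted variant classes
#'   (SNV, single-base indel, 2-3 nt multi-nucleotide difference).
#' @param deFraction fraction of genes differentially expressed.
#' @param deFold fold multiplier applied to differentially expressed genes.
#' @param abundanceLogSd log-scale s.d. of baseline per-gene abundance.
#' @param seed root seed; every stochastic stage derives its own stream.
#' @return A validated `SimConfig` object.
#' @examples
#' cfg <- SimConfig(nGenes = 5, nReadsPerSample = 100, seed = 1)
#' cfg
#' @aliases SimConfig-class
#' @export
SimConfig <- function(nGenes = 20L,
                      geneLengthMean = 1500,
                      geneLengthSd = 400,
                      nReadsPerSample = 2000L,
                      readLengthMeanT = 376,
                      readLengthSdT = 148,
                      readLengthMeanA = 358,
                      readLengthSdA = 146,
                      readLengthMin = 50,
                      readLengthMax = 600,
                      subErrorRate = 0.001,
                      homopolymerIndelCoeff = 0.005,
                      snpRate = 1e-3,
                      zygosityMix = c(7260, 7315, 11530, 4386) / 30491,
                      variantClassMix = c(snv = 0.90, indel = 0.05,
                                          mnp = 0.05),
                      deFraction = 0.1,
                      deFold = 2,
                      abundanceLogSd = 1,
                      seed = 1L) {
  new("SimConfig",
      nGenes = as.integer(nGenes), geneLengthMean = geneLengthMean,
      geneLengthSd = geneLengthSd,
      nReadsPerSample = as.integer(nReadsPerSample),
      readLengthMeanT = readLengthMeanT, readLengthSdT = readLengthSdT,
      readLengthMeanA = readLengthMeanA, readLengthSdA = readLengthSdA,
      readLengthMin = readLengthMin, readLengthMax = readLengthMax,
      subErrorRate = subErrorRate,
      homopolymerIndelCoeff = homopolymerIndelCoeff,
      snpRate = snpRate, zygosityMix = as.numeric(zygosityMix),
      variantClassMix = as.numeric(variantClassMix),
      deFraction = deFraction, deFold = deFold,
      abundanceLogSd = abundanceLogSd, seed = as.integer(seed))
}

setClass("SimConfig", representation(
  nGenes = "integer", geneLengthMean = "numeric", geneLengthSd = "numeric",
  nReadsPerSample = "integer",
  readLengthMeanT = "numeric", readLengthSdT = "numeric",
  readLengthMeanA = "numeric", readLengthSdA = "numeric",
  readLengthMin = "numeric", readLengthMax = "numeric",
  subErrorRate = "numeric", homopolymerIndelCoeff = "numeric",
  snpRate = "numeric", zygosityMix = "numeric",
  variantClassMix = "numeric",
  deFraction = "numeric", deFold = "numeric", abundanceLogSd = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@geneLengthMean <= 0 || object@geneLengthSd < 0)
    msg <- c(msg, "gene length parameters must be positive")
  if (object@nReadsPerSample < 0L)
    msg <- c(msg, "nReadsPerSample must be >= 0")
  if (object@readLengthMin < 1)
    msg <- c(msg, "readLengthMin must be >= 1")
  if (object@readLengthMax < object@readLengthMin)
    msg <- c(msg, "readLengthMax must be >= readLengthMin")
  for (p in c("subErrorRate", "homopolymerIndelCoeff", "snpRate",
              "deFraction")) {
    v <- slot(object, p)
    if (!is.finite(v) || v < 0 || v > 1)
      msg <- c(msg, paste(p, "must lie in [0, 1]"))
  }
  if (length(object@zygosityMix) != 4L ||
      any(object@zygosityMix < 0) ||
      abs(sum(object@zygosityMix) - 1) > 1e-9)
    msg <- c(msg, "zygosityMix must be 4 probabilities summing to 1")
  if (length(object@variantClassMix) != 3L ||
      any(object@variantClassMix < 0) ||
      abs(sum(object@variantClassMix) - 1) > 1e-9)
    msg <- c(msg, "variantClassMix must be 3 probabilities summing to 1")
  if (object@deFold <= 0) msg <- c(msg, "deFold must be > 0")
  if (object@abundanceLogSd < 0)
    msg <- c(msg, "abundanceLogSd must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,",
      object@nReadsPerSample, "reads/sample\n")
  cat(sprintf("  read length T ~ N(%g, %g), A ~ N(%g, %g), trunc [%g, %g]\n",
              object@readLengthMeanT, object@readLengthSdT,
              object@readLengthMeanA, object@readLengthSdA,
              object@readLengthMin, object@readLengthMax))
  cat(sprintf("  sub error %g, homopolymer indel coeff %g, snp rate %g\n",
              object@subErrorRate, object@homopolymerIndelCoeff,
              object@snpRate))
  cat(sprintf("  DE: fraction %g at fold %g; seed %d\n",
              object@deFraction, object@deFold, object@seed))
})

#' Mapping thresholds for read classification
#'
#' Numeric definitions behind the six mapping categories (fully mapped,
#' partially mapped, unmapped, repeats, chimeric, too short to map). The
#' identity/coverage pair defaults to the 95%-identity-over-90%-of-length
#' rule used for cDNA-mode mapping of pyrosequencing reads.
#'
#' @param minIdentity minimum alignment identity for a mapped read.
#' @param minCover fraction of the read that the best alignment must cover
#'   for the read to count as fully mapped.
#' @param partialMinCover lower coverage bound separating partially mapped
#'   from unmapped.
#' @param tooShortLen reads shorter than this are "too short to map".
#' @param chimeraMinSegment minimum length of each of the two disjoint read
#'   segments of a chimeric read.
#' @param chimeraMinGap minimum reference gap for two same-reference
#'   segments to count as chimeric.
#' @param repeatIdentityMargin identity margin within which a second locus
#'   makes the read a repeat.
#' @return A validated `MappingThresholds` object.
#' @examples
#' MappingThresholds()
#' @aliases MappingThresholds-class
#' @export
MappingThresholds <- function(minIdentity = 0.95, minCover = 0.90,
                              partialMinCover = 0.50,
                              tooShortLen = 50L,
                              chimeraMinSegment = 30L,
                              chimeraMinGap = 10000L,
                              repeatIdentityMargin = 0.01) {
  new("MappingThresholds", minIdentity = minIdentity, minCover = minCover,
      partialMinCover = partialMinCover,
      tooShortLen = as.integer(tooShortLen),
      chimeraMinSegment = as.integer(chimeraMinSegment),
      chimeraMinGap = as.integer(chimeraMinGap),
      repeatIdentityMargin = repeatIdentityMargin)
}

setClass("MappingThresholds", representation(
  minIdentity = "numeric", minCover = "numeric",
  partialMinCover = "numeric", tooShortLen = "integer",
  chimeraMinSegment = "integer", chimeraMinGap = "integer",
  repeatIdentityMargin = "numeric"))

setValidity("MappingThresholds", function(object) {
  msg <- character()
  for (p in c("minIdentity", "minCover", "partialMinCover")) {
    v <- slot(object, p)
    if (!is.finite(v) || v <= 0 || v > 1)
      msg <- c(msg, paste(p, "must lie in (0, 1]"))
  }
  if (length(msg) == 0L && object@partialMinCover > object@minCover)
    msg <- c(msg, "partialMinCover must be <= minCover")
  if (object@tooShortLen < 1L || object@chimeraMinSegment < 1L ||
      object@chimeraMinGap < 1L)
    msg <- c(msg, "length thresholds must be positive")
  if (object@repeatIdentityMargin < 0 || object@repeatIdentityMargin >= 1)
    msg <- c(msg, "repeatIdentityMargin must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MappingThresholds", function(object) {
  cat(sprintf(
    "MappingThresholds: identity >= %g over >= %g of read (partial >= %g)\n",
    object@minIdentity, object@minCover, object@partialMinCover))
  cat(sprintf(
    "  too short < %d; chimera segment >= %d, gap >= %d; repeat margin %g\n",
    object@tooShortLen, object@chimeraMinSegment, object@chimeraMinGap,
    object@repeatIdentityMargin))
})

#' Filters defining high-confidence SNPs
#'
#' The tiered retention rules applied to candidate differences: an error
#' floor (pooled minor-allele fractions of 1-5% are treated as sequencing
#' error), a 95% consensus rule separating species-level fixed differences
#' from within-species polymorphisms, and the minor-allele-fraction /
#' read-depth tiers used for SNP retention. Tier A requires the minor
#' allele at >= 25% of reads in every sample showing both alleles and more
#' than three reads per allele in some individual; tier B is the same with
#' exactly three; tier C requires at least three minor-allele reads summed
#' over the two individuals.
#'
#' @param minMinorFrac within-sample minor-allele fraction floor (tiers A/B).
#' @param minReadsPerAllele reads per allele per individual (tiers A/B).
#' @param errorFloorLow,errorFloorHigh pooled minor-allele fraction band
#'   treated as sequencing error.
#' @param fixedDiffConsensus consensus fraction above which a non-reference
#'   allele is a fixed difference.
#' @return A validated `SnpFilterConfig` object.
#' @examples
#' SnpFilterConfig()
#' @aliases SnpFilterConfig-class
#' @export
SnpFilterConfig <- function(minMinorFrac = 0.25, minReadsPerAllele = 3L,
                            errorFloorLow = 0.01, errorFloorHigh = 0.05,
                            fixedDiffConsensus = 0.95) {
  new("SnpFilterConfig", minMinorFrac = minMinorFrac,
      minReadsPerAllele = as.integer(minReadsPerAllele),
      errorFloorLow = errorFloorLow, errorFloorHigh = errorFloorHigh,
      fixedDiffConsensus = fixedDiffConsensus)
}

setClass("SnpFilterConfig", representation(
  minMinorFrac = "numeric", minReadsPerAllele = "integer",
  errorFloorLow = "numeric", errorFloorHigh = "numeric",
  fixedDiffConsensus = "numeric"))

setValidity("SnpFilterConfig", function(object) {
  msg <- character()
  if (!(object@errorFloorLow > 0 &&
        object@errorFloorLow <= object@errorFloorHigh &&
        object@errorFloorHigh < object@minMinorFrac))
    msg <- c(msg,
             "need 0 < errorFloorLow <= errorFloorHigh < minMinorFrac")
  if (object@fixedDiffConsensus <= 0.5 || object@fixedDiffConsensus > 1)
    msg <- c(msg, "fixedDiffConsensus must lie in (0.5, 1]")
  if (object@minReadsPerAllele < 1L)
    msg <- c(msg, "minReadsPerAllele must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SnpFilterConfig", function(object) {
  cat(sprintf(
    "SnpFilterConfig: minor frac >= %g, reads/allele >= %d,\n",
    object@minMinorFrac, object@minReadsPerAllele))
  cat(sprintf("  error floor (%g, %g], fixed-difference consensus >= %g\n",
              object@errorFloorLow, object@errorFloorHigh,
              object@fixedDiffConsensus))
})

#' Differential-expression screen settings
#'
#' @param minFold minimum fold difference of library-normalized proportions.
#' @param maxP two-sided p-value cutoff.
#' @param zeroCountPolicy how a zero count in one library is handled when
#'   computing fold change: `"undefined"` reports an undefined fold (the
#'   direction of the non-zero side is kept), `"pseudocount_1"` adds one
#'   read to both counts.
#' @return A validated `ScreenConfig` object.
#' @examples
#' ScreenConfig()
#' @aliases ScreenConfig-class
#' @export
ScreenConfig <- function(minFold = 2.0, maxP = 0.05,
                         zeroCountPolicy = c("undefined", "pseudocount_1")) {
  new("ScreenConfig", minFold = minFold, maxP = maxP,
      zeroCountPolicy = match.arg(zeroCountPolicy))
}

setClass("ScreenConfig", representation(
  minFold = "numeric", maxP = "numeric", zeroCountPolicy = "character"))

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (object@minFold < 1) msg <- c(msg, "minFold must be >= 1")
  if (object@maxP <= 0 || object@maxP >= 1)
    msg <- c(msg, "maxP must lie in (0, 1)")
  if (!object@zeroCountPolicy %in% c("undefined", "pseudocount_1"))
    msg <- c(msg, "unknown zeroCountPolicy")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScreenConfig", function(object) {
  cat(sprintf("ScreenConfig: fold >= %g and p < %g (zero counts: %s)\n",
              object@minFold, object@maxP, object@zeroCountPolicy))
})

#' Planted truth for a simulated two-individual experiment
#'
#' Container binding the three truth tables of a simulation: planted
#' genotypes (one row per variant site, with per-individual diploid
#' genotypes), expected per-gene abundance proportions per sample, and
#' per-read origins (gene, haplotype, start, strand, error counts).
#'
#' @param genotypes data.frame of planted variant sites.
#' @param abundances data.frame of per-gene expected proportions.
#' @param readOrigins data.frame of per-read origins (may be empty before
#'   reads are simulated).
#' @return A validated `TruthSet` object.
#' @aliases TruthSet-class truthGenotypes truthAbundances truthReadOrigins
#' @export
TruthSet <- function(genotypes, abundances,
                     readOrigins = data.frame()) {
  new("TruthSet", genotypes = genotypes, abundances = abundances,
      readOrigins = readOrigins)
}

setClass("TruthSet", representation(
  genotypes = "data.frame", abundances = "data.frame",
  readOrigins = "data.frame"))

setValidity("TruthSet", function(object) {
  msg <- character()
  g <- object@genotypes
  need <- c("gene", "position", "ref", "alt", "class", "category",
            "gtTame", "gtAggr")
  if (nrow(g) && !all(need %in% names(g)))
    msg <- c(msg, paste("genotypes needs columns:",
                        paste(need, collapse = ", ")))
  a <- object@abundances
  if (nrow(a)) {
    if (!all(c("gene", "propTame", "propAggr") %in% names(a)))
      msg <- c(msg, "abundances needs gene, propTame, propAggr")
    else if (abs(sum(a$propTame) - 1) > 1e-9 ||
             abs(sum(a$propAggr) - 1) > 1e-9)
      msg <- c(msg, "per-sample abundances must sum to 1")
  }
  ro <- object@readOrigins
  if (nrow(ro) && nrow(a) && !all(ro$gene %in% a$gene))
    msg <- c(msg, "read origins reference unknown genes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@genotypes), "planted sites,",
      nrow(object@abundances), "genes,",
      nrow(object@readOrigins), "read origins\n")
})

#' @describeIn TruthSet planted genotype table.
#' @param x a `TruthSet`.
#' @export
truthGenotypes <- function(x) x@genotypes

#' @describeIn TruthSet expected per-gene abundance proportions.
#' @export
truthAbundances <- function(x) x@abundances

#' @describeIn TruthSet per-read origin table.
#' @export
truthReadOrigins <- function(x) x@readOrigins
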