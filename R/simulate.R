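#' Simulate a transcript reference set with region annotation
#'
#' Draws `nGenes` transcript-scale sequences under a uniform base model,
#' with lengths from a truncated normal. Each gene long enough to carry
#' structure is annotated with 5'UTR / coding / intron / 3'UTR
#' sub-intervals (treating the simulated unit as a genomic segment), so
#' that region classification of variant positions can be tested against
#' a known layout.
#'
#' @param config a [SimConfig].
#' @param forceLength optional single length (bases) overriding the length
#'   model for every gene.
#' @return A list with `sequences` (a named [Biostrings::DNAStringSet]) and
#'   `annotation` (a [GenomicRanges::GRanges] with a `type` column in
#'   coding/utr/intron).
#' @examples
#' ref <- simulateTranscriptome(SimConfig(nGenes = 3, seed = 7))
#' ref$sequences
#' @export
simulateTranscriptome <- function(config, forceLength = NULL) {
  stopifnot(is(config, "SimConfig"))
  withStageSeed(config@seed, "transcriptome", {
    n <- config@nGenes
    lens <- if (is.null(forceLength)) {
      round(rtruncnorm(n, config@geneLengthMean, config@geneLengthSd,
                       lower = max(100, config@readLengthMin),
                       upper = config@geneLengthMean +
                         6 * config@geneLengthSd))
    } else rep(as.integer(forceLength), n)
    ids <- sprintf("gene%03d", seq_len(n))
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = "")
    }, character(1))
    sequences <- Biostrings::DNAStringSet(setNames(seqs, ids))
    annotation <- .annotateGeneStructure(ids, lens)
    list(sequences = sequences, annotation = annotation)
  })
}

# Fixed structural proportions: utr5 10%, coding 20%, intron 10%,
# coding 20%, intron 10%, coding 15%, utr3 15%. Genes under 200 bases are
# annotated as a single coding interval.
.annotateGeneStructure <- function(ids, lens) {
  parts <- lapply(seq_along(ids), function(i) {
    L <- lens[i]
    if (L < 200L) {
      return(data.frame(gene = ids[i], start = 1L, end = L,
                        type = "coding"))
    }
    frac <- c(0.10, 0.20, 0.10, 0.20, 0.10, 0.15, 0.15)
    type <- c("utr", "coding", "intron", "coding", "intron", "coding",
              "utr")
    cuts <- unique(c(0L, pmin(L, round(cumsum(frac) * L))))
    cuts[length(cuts)] <- L
    data.frame(gene = ids[i], start = head(cuts, -1) + 1L,
               end = cuts[-1], type = type[seq_len(length(cuts) - 1L)])
  })
  tab <- do.call(rbind, parts)
  GenomicRanges::GRanges(tab$gene,
                         IRanges::IRanges(tab$start, tab$end),
                         type = tab$type)
}

#' Plant variant sites and build diploid haplotypes for two individuals
#'
#' Variant sites are placed along each reference at rate `snpRate`, with a
#' minimum spacing of four bases (colliding sites are thinned with a
#' warning). Each site draws a variant class (SNV, single-base indel, or
#' 2-3 nt multi-nucleotide difference) and one of four joint zygosity
#' classes for the (tame, aggressive) pair. Haplotype sequences carrying
#' the planted alleles are returned for each of the four chromosome
#' copies; heterozygous individuals carry the alternate allele on their
#' second copy.
#'
#' @param references a named [Biostrings::DNAStringSet] of transcripts.
#' @param config a [SimConfig].
#' @return A list with `truth` (a [TruthSet] whose genotype table has one
#'   row per planted site, positions 1-based in reference coordinates, and
#'   diploid genotypes in "0/0", "0/1", "1/1" notation) and `haplotypes`
#'   (a list of four [Biostrings::DNAStringSet]s named tame1, tame2,
#'   aggressive1, aggressive2).
#' @examples
#' ref <- simulateTranscriptome(SimConfig(nGenes = 2, snpRate = 0.01))
#' sim <- simulateIndividuals(ref$sequences, SimConfig(nGenes = 2,
#'                                                     snpRate = 0.01))
#' head(truthGenotypes(sim$truth))
#' @export
simulateIndividuals <- function(references, config) {
  stopifnot(is(config, "SimConfig"))
  if (length(references) == 0L)
    stop("reference set is empty", call. = FALSE)
  withStageSeed(config@seed, "individuals", {
    categories <- c("homT.homA", "hetT.homA", "homT.hetA", "hetT.hetA")
    sites <- lapply(seq_along(references), function(gi) {
      L <- Biostrings::width(references)[gi]
      nSites <- rbinom(1L, L, config@snpRate)
      if (nSites == 0L || L < 12L)
        return(NULL)
      pos <- sort(sample.int(L - 8L, min(nSites, L - 8L)) + 4L)
      keep <- c(TRUE, diff(pos) >= 4L)
      if (any(!keep))
        warning("thinned ", sum(!keep),
                " colliding variant sites in ",
                names(references)[gi], call. = FALSE)
      pos <- pos[keep]
      if (!length(pos)) return(NULL)
      data.frame(gene = names(references)[gi], position = pos)
    })
    sites <- do.call(rbind, sites)
    if (is.null(sites) || nrow(sites) == 0L) {
      truth <- TruthSet(genotypes = data.frame(
        gene = character(), position = integer(), ref = character(),
        alt = character(), class = character(), category = character(),
        gtTame = character(), gtAggr = character()),
        abundances = data.frame())
      haps <- list(tame1 = references, tame2 = references,
                   aggressive1 = references, aggressive2 = references)
      return(list(truth = truth, haplotypes = haps))
    }
    n <- nrow(sites)
    cls <- sample(c("SNV", "indel", "MNP"), n, replace = TRUE,
                  prob = config@variantClassMix)
    cat4 <- sample(categories, n, replace = TRUE,
                   prob = config@zygosityMix)
    refA <- altA <- character(n)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n)) {
      g <- sites$gene[i]; p <- sites$position[i]
      refBase <- as.character(Biostrings::subseq(references[[g]], p, p))
      if (cls[i] == "SNV") {
        refA[i] <- refBase
        altA[i] <- sample(setdiff(bases, refBase), 1L)
      } else if (cls[i] == "indel") {
        if (runif(1) < 0.5) {          # insertion after p
          refA[i] <- refBase
          altA[i] <- paste0(refBase, sample(bases, 1L))
        } else {                        # deletion of base p + 1
          refA[i] <- as.character(
            Biostrings::subseq(references[[g]], p, p + 1L))
          altA[i] <- refBase
        }
      } else {                          # 2-3 nt difference
        w <- sample(2:3, 1L)
        refA[i] <- as.character(
          Biostrings::subseq(references[[g]], p, p + w - 1L))
        altA[i] <- paste(vapply(strsplit(refA[i], "")[[1]],
                                function(b) sample(setdiff(bases, b), 1L),
                                character(1)), collapse = "")
      }
    }
    # Joint genotypes; for hom/hom the carrier of the alternate allele is
    # drawn at random, as is the homozygous allele of the non-het
    # individual in the het/hom classes.
    gtT <- gtA <- character(n)
    coin <- runif(n) < 0.5
    for (i in seq_len(n)) {
      gtT[i] <- switch(cat4[i],
        homT.homA = if (coin[i]) "1/1" else "0/0",
        hetT.homA = "0/1",
        homT.hetA = if (coin[i]) "1/1" else "0/0",
        hetT.hetA = "0/1")
      gtA[i] <- switch(cat4[i],
        homT.homA = if (coin[i]) "0/0" else "1/1",
        hetT.homA = if (coin[i]) "0/0" else "1/1",
        homT.hetA = "0/1",
        hetT.hetA = "0/1")
    }
    geno <- data.frame(gene = sites$gene, position = sites$position,
                       ref = refA, alt = altA, class = cls,
                       category = cat4, gtTame = gtT, gtAggr = gtA,
                       stringsAsFactors = FALSE)
    haps <- list(
      tame1 = .applyAlleles(references, geno, geno$gtTame %in% "1/1"),
      tame2 = .applyAlleles(references, geno,
                            geno$gtTame %in% c("0/1", "1/1")),
      aggressive1 = .applyAlleles(references, geno,
                                  geno$gtAggr %in% "1/1"),
      aggressive2 = .applyAlleles(references, geno,
                                  geno$gtAggr %in% c("0/1", "1/1")))
    truth <- TruthSet(genotypes = geno, abundances = data.frame())
    list(truth = truth, haplotypes = haps)
  })
}

.applyAlleles <- function(references, geno, carry) {
  out <- references
  g <- geno[carry, , drop = FALSE]
  for (gene in unique(g$gene)) {
    rows <- g[g$gene == gene, , drop = FALSE]
    at <- IRanges::IRanges(rows$position,
                           rows$position + nchar(rows$ref) - 1L)
    out[[gene]] <- Biostrings::replaceAt(
      references[[gene]], at, Biostrings::DNAStringSet(rows$alt))
  }
  out
}

#' Simulate per-gene expression proportions for the two libraries
#'
#' Baseline abundances are log-normal with log-scale s.d.
#' `abundanceLogSd`, normalized to proportions. A fraction `deFraction`
#' of genes is multiplied by `deFold` in one designated sample (half of
#' them up in each library) and both samples are renormalized; with
#' `deFold = 1` no gene is marked differentially expressed.
#'
#' @param config a [SimConfig].
#' @return data.frame with gene, propTame, propAggr, isDE, direction
#'   ("T>A", "A>T", or "none").
#' @examples
#' head(simulateExpression(SimConfig(nGenes = 10, deFraction = 0.2)))
#' @export
simulateExpression <- function(config) {
  stopifnot(is(config, "SimConfig"))
  withStageSeed(config@seed, "expression", {
    n <- config@nGenes
    ids <- sprintf("gene%03d", seq_len(n))
    base <- exp(rnorm(n, 0, config@abundanceLogSd))
    pT <- pA <- base
    nDE <- if (config@deFold == 1) 0L else round(config@deFraction * n)
    isDE <- rep(FALSE, n)
    direction <- rep("none", n)
    if (nDE > 0L) {
      de <- sample.int(n, nDE)
      upT <- de[seq_len(ceiling(nDE / 2))]
      upA <- setdiff(de, upT)
      pT[upT] <- pT[upT] * config@deFold
      pA[upA] <- pA[upA] * config@deFold
      isDE[de] <- TRUE
      direction[upT] <- "T>A"
      direction[upA] <- "A>T"
    }
    data.frame(gene = ids, propTame = pT / sum(pT),
               propAggr = pA / sum(pA), isDE = isDE,
               direction = direction, stringsAsFactors = FALSE)
  })
}

#' Simulate 454-style reads from diploid haplotypes
#'
#' For each library, reads pick a gene multinomially by abundance, a
#' haplotype copy uniformly, a strand uniformly, and a start uniform
#' along the chosen haplotype. Read lengths follow the library's
#' truncated normal; a read longer than its transcript is truncated to
#' the transcript and flagged. Sequencing errors are substitutions at
#' `subErrorRate` per base plus homopolymer indels: a run of length r
#' gains or loses one unit with probability
#' `min(homopolymerIndelCoeff * (r - 1), 0.1)`.
#'
#' @param haplotypes the four-haplotype list from [simulateIndividuals()].
#' @param abundances the proportion table from [simulateExpression()].
#' @param config a [SimConfig].
#' @return A list with one element per sample (`tame`, `aggressive`), each
#'   containing `reads` (a [Biostrings::DNAStringSet]), `qualities`
#'   (a [Biostrings::BStringSet] of Sanger-encoded qualities) and
#'   `origins` (data.frame: readId, gene, haplotype, start, strand,
#'   trueLength, nSub, nIndel, truncated). Origins record the error-free
#'   placement in haplotype coordinates.
#' @examples
#' cfg <- SimConfig(nGenes = 2, nReadsPerSample = 10, seed = 3)
#' ref <- simulateTranscriptome(cfg)
#' ind <- simulateIndividuals(ref$sequences, cfg)
#' ab <- simulateExpression(cfg)
#' rd <- simulateReads(ind$haplotypes, ab, cfg)
#' rd$tame$reads
#' @export
simulateReads <- function(haplotypes, abundances, config) {
  stopifnot(is(config, "SimConfig"))
  if (abs(sum(abundances$propTame) - 1) > 1e-9 ||
      abs(sum(abundances$propAggr) - 1) > 1e-9)
    stop("abundance proportions must sum to 1 per sample", call. = FALSE)
  res <- list()
  for (sample_ in c("tame", "aggressive")) {
    stage <- if (sample_ == "tame") "reads_tame" else "reads_aggressive"
    res[[sample_]] <- withStageSeed(config@seed, stage, {
      .simulateSampleReads(haplotypes, abundances, config, sample_)
    })
  }
  res
}

.simulateSampleReads <- function(haplotypes, abundances, config, sample_) {
  n <- config@nReadsPerSample
  prop <- if (sample_ == "tame") abundances$propTame else
    abundances$propAggr
  lmean <- if (sample_ == "tame") config@readLengthMeanT else
    config@readLengthMeanA
  lsd <- if (sample_ == "tame") config@readLengthSdT else
    config@readLengthSdA
  prefix <- if (sample_ == "tame") "T" else "A"
  hapNames <- if (sample_ == "tame") c("tame1", "tame2") else
    c("aggressive1", "aggressive2")
  if (n == 0L) {
    return(list(reads = Biostrings::DNAStringSet(),
                qualities = Biostrings::BStringSet(),
                origins = data.frame()))
  }
  geneIdx <- sample.int(length(prop), n, replace = TRUE, prob = prop)
  genes <- abundances$gene[geneIdx]
  hapIdx <- sample.int(2L, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  lens <- round(rtruncnorm(n, lmean, lsd, config@readLengthMin,
                           config@readLengthMax))
  seqs <- character(n)
  starts <- integer(n)
  truncated <- logical(n)
  nSub <- nIndel <- integer(n)
  trueLen <- integer(n)
  for (i in seq_len(n)) {
    hap <- haplotypes[[hapNames[hapIdx[i]]]][[genes[i]]]
    L <- length(hap)
    len <- lens[i]
    if (L < len) {
      len <- L
      truncated[i] <- TRUE
    }
    start <- if (L == len) 1L else sample.int(L - len + 1L, 1L)
    frag <- as.character(Biostrings::subseq(hap, start, start + len - 1L))
    if (strand[i] == "-")
      frag <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(frag)))
    err <- .applySequencingErrors(frag, config)
    seqs[i] <- err$seq
    starts[i] <- start
    trueLen[i] <- len
    nSub[i] <- err$nSub
    nIndel[i] <- err$nIndel
  }
  ids <- sprintf("%s%06d", prefix, seq_len(n))
  reads <- Biostrings::DNAStringSet(setNames(seqs, ids))
  # Constant Phred 35 base quality; the error model is parameterized
  # directly, qualities are carried for format fidelity only.
  quals <- Biostrings::BStringSet(setNames(
    vapply(nchar(seqs), function(k)
      paste(rep(rawToChar(as.raw(33 + 35)), k), collapse = ""),
      character(1)), ids))
  origins <- data.frame(
    readId = ids, sample = sample_, gene = genes,
    haplotype = hapNames[hapIdx], start = starts, strand = strand,
    trueLength = trueLen, nSub = nSub, nIndel = nIndel,
    truncated = truncated, stringsAsFactors = FALSE)
  list(reads = reads, qualities = quals, origins = origins)
}

.applySequencingErrors <- function(seq, config) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  nIndel <- 0L
  if (config@homopolymerIndelCoeff > 0) {
    r <- rle(chars)
    long <- which(r$lengths >= 2L)
    if (length(long)) {
      p <- pmin(config@homopolymerIndelCoeff * (r$lengths[long] - 1L),
                0.1)
      hit <- long[runif(length(long)) < p]
      if (length(hit)) {
        delta <- sample(c(-1L, 1L), length(hit), replace = TRUE)
        r$lengths[hit] <- r$lengths[hit] + delta
        nIndel <- length(hit)
        chars <- inverse.rle(r)
      }
    }
  }
  nSub <- 0L
  if (config@subErrorRate > 0 && length(chars)) {
    hit <- which(runif(length(chars)) < config@subErrorRate)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      nSub <- length(hit)
    }
  }
  list(seq = paste(chars, collapse = ""), nSub = nSub, nIndel = nIndel)
}

#' Run the full simulation stage
#'
#' Convenience wrapper chaining [simulateTranscriptome()],
#' [simulateIndividuals()], [simulateExpression()] and [simulateReads()],
#' returning everything downstream stages need plus the complete
#' [TruthSet].
#'
#' @param config a [SimConfig].
#' @return list with `references`, `annotation`, `haplotypes`, `truth`
#'   (a [TruthSet] with genotypes, abundances and read origins filled in)
#'   and `reads` (per-sample read sets as in [simulateReads()]).
#' @examples
#' sim <- simulateExperiment(SimConfig(nGenes = 3, nReadsPerSample = 20))
#' sim$truth
#' @export
simulateExperiment <- function(config) {
  ref <- simulateTranscriptome(config)
  ind <- simulateIndividuals(ref$sequences, config)
  ab <- simulateExpression(config)
  rd <- simulateReads(ind$haplotypes, ab, config)
  origins <- rbind(rd$tame$origins, rd$aggressive$origins)
  truth <- TruthSet(genotypes = truthGenotypes(ind$truth),
                    abundances = ab, readOrigins = origins)
  list(references = ref$sequences, annotation = ref$annotation,
       haplotypes = ind$haplotypes, truth = truth, reads = rd)
}
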