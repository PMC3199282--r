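## Pipeline orchestration: simulate -> map -> call -> coverage -> de,
## with on-disk artifacts, table bundle and a JSON run manifest.

#' Run the analysis pipeline on simulated data
#'
#' Chains the simulation, mapping, variant-calling, coverage and
#' expression stages, writing each stage's standard outputs under
#' `outDir` and returning all in-memory results. Stages may be run
#' selectively; later stages reuse the in-memory results of earlier ones
#' from the same call, or reload what they need from `outDir` when
#' resuming a previous run.
#'
#' @param simConfig a [SimConfig].
#' @param outDir output directory (created if needed).
#' @param thresholds a [MappingThresholds].
#' @param filterConfig a [SnpFilterConfig].
#' @param screenConfig a [ScreenConfig].
#' @param stages ordered subset of
#'   c("simulate", "map", "call", "coverage", "de").
#' @return (invisibly) a list with the per-stage results: `sim`,
#'   `alignments`, `mappingSummary`, `pileup`, `records`, `census`,
#'   `divergence`, `coverage`, `saturation`, `de`, `ma`, plus `manifest`.
#' @export
runPipeline <- function(simConfig = SimConfig(),
                        outDir,
                        thresholds = MappingThresholds(),
                        filterConfig = SnpFilterConfig(),
                        screenConfig = ScreenConfig(),
                        stages = c("simulate", "map", "call",
                                   "coverage", "de")) {
  stopifnot(is(simConfig, "SimConfig"))
  known <- c("simulate", "map", "call", "coverage", "de")
  if (!all(stages %in% known))
    stop("unknown stages: ",
         paste(setdiff(stages, known), collapse = ", "), call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if ("simulate" %in% stages) {
    res$sim <- simulateExperiment(simConfig)
    Biostrings::writeXStringSet(res$sim$references,
                                file.path(outDir, "references.fasta"))
    writeReadsFastq(res$sim$reads$tame,
                    file.path(outDir, "reads_tame.fastq"))
    writeReadsFastq(res$sim$reads$aggressive,
                    file.path(outDir, "reads_aggressive.fastq"))
    writeGenotypesVcf(truthGenotypes(res$sim$truth),
                      res$sim$references,
                      file.path(outDir, "truth_genotypes.vcf"))
    writeTruthSam(truthReadOrigins(res$sim$truth), res$sim$references,
                  file.path(outDir, "truth_alignments.sam"))
    .writeTsv(truthAbundances(res$sim$truth),
              file.path(outDir, "truth_abundances.tsv"))
    .writeTsv(truthReadOrigins(res$sim$truth),
              file.path(outDir, "truth_read_origins.tsv"))
    ann <- res$sim$annotation
    .writeTsv(data.frame(gene = as.character(
                           GenomicRanges::seqnames(ann)),
                         start = GenomicRanges::start(ann),
                         end = GenomicRanges::end(ann),
                         type = ann$type),
              file.path(outDir, "annotation.tsv"))
  }

  loadRefs <- function(stage) {
    if (!is.null(res$sim)) return(res$sim$references)
    p <- file.path(outDir, "references.fasta")
    if (!file.exists(p))
      stop("stage '", stage, "' needs references: missing ", p,
           call. = FALSE)
    Biostrings::readDNAStringSet(p)
  }
  loadReads <- function(sample_) {
    if (!is.null(res$sim)) return(res$sim$reads[[sample_]]$reads)
    p <- file.path(outDir, paste0("reads_", sample_, ".fastq"))
    if (!file.exists(p))
      stop("stage 'map' needs reads: missing ", p, call. = FALSE)
    Biostrings::readDNAStringSet(p, format = "fastq")
  }

  if ("map" %in% stages) {
    refs <- loadRefs("map")
    alnT <- alignReads(loadReads("tame"), refs, thresholds,
                       sample = "tame")
    alnA <- alignReads(loadReads("aggressive"), refs, thresholds,
                       sample = "aggressive")
    res$alignments <- rbind(alnT, alnA)
    res$mappingSummary <- classifyReads(res$alignments)
    .writeTsv(res$alignments, file.path(outDir, "alignments.tsv"))
    .writeTsv(res$mappingSummary,
              file.path(outDir, "mapping_summary.tsv"))
  }

  loadAlignments <- function(stage) {
    if (!is.null(res$alignments)) return(res$alignments)
    p <- file.path(outDir, "alignments.tsv")
    if (!file.exists(p))
      stop("stage '", stage, "' needs alignments: missing ", p,
           call. = FALSE)
    read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }

  if ("call" %in% stages) {
    refs <- loadRefs("call")
    aln <- loadAlignments("call")
    res$pileup <- buildPileup(aln, refs)
    recs <- enumerateDifferences(res$pileup)
    recs <- partitionDifferences(recs, filterConfig)
    recs <- filterHighConfidence(recs, filterConfig)
    recs <- classifyZygosity(recs, filterConfig)
    res$records <- recs
    res$census <- zygosityCensus(recs[recs$retained, , drop = FALSE])
    mappedBases <- nrow(unique(res$pileup[, c("referenceId",
                                              "position")]))
    res$divergence <- divergenceSummary(
      max(1L, mappedBases),
      nFixed = sum(recs$status == "fixed_difference"),
      nPolymorphic = sum(recs$status == "polymorphism"),
      nExcluded = sum(recs$status == "excluded_error_floor"))
    writeSnpVcf(recs[recs$retained, , drop = FALSE],
                file.path(outDir, "snps.vcf"), refs)
    .writeTsv(recs[recs$class != "SNV", , drop = FALSE],
              file.path(outDir, "differences_indel_mnp.tsv"))
    .writeTsv(recs, file.path(outDir, "differences_all.tsv"))
    jsonlite::write_json(res$divergence,
                         file.path(outDir, "divergence.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("coverage" %in% stages) {
    refs <- loadRefs("coverage")
    aln <- loadAlignments("coverage")
    res$coverage <- breadthOfCoverage(aln, refs)
    .writeTsv(res$coverage, file.path(outDir, "coverage.tsv"))
    mapped <- ifelse(aln$category %in% c("fully", "partially"),
                     aln$referenceId, NA_character_)
    unit <- max(1L, floor(length(mapped) / 10))
    res$saturation <- saturationCurve(mapped, unit, names(refs),
                                      seed = simConfig@seed)
    .writeTsv(res$saturation, file.path(outDir, "saturation.tsv"))
  }

  if ("de" %in% stages) {
    refs <- loadRefs("de")
    aln <- loadAlignments("de")
    use <- aln[aln$category %in% c("fully", "partially"), , drop = FALSE]
    counts <- data.frame(gene = names(refs), stringsAsFactors = FALSE)
    counts$countT <- vapply(counts$gene, function(g)
      sum(use$referenceId == g & use$sample == "tame"), integer(1))
    counts$countA <- vapply(counts$gene, function(g)
      sum(use$referenceId == g & use$sample == "aggressive"),
      integer(1))
    res$de <- deScreen(deTable(counts, config = screenConfig),
                       screenConfig)
    res$ma <- maData(counts)
    .writeTsv(res$de$table, file.path(outDir, "de_results.tsv"))
    .writeTsv(res$ma$post, file.path(outDir, "ma_post.tsv"))
    .writeTsv(res$ma$pre, file.path(outDir, "ma_pre.tsv"))
  }

  res$manifest <- list(
    package = "VulpesTx",
    version = as.character(utils::packageVersion("VulpesTx")),
    seed = simConfig@seed, stages = stages,
    nGenes = simConfig@nGenes,
    nReadsPerSample = simConfig@nReadsPerSample)
  jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Write the report table bundle
#'
#' Emits the census and summary tables of a pipeline result in the
#' conventional layouts: mapping-category summary (fully, partially,
#' unmapped, repeats, chimeric, too short), the 2x2 zygosity census, the
#' region census, and the expression table ordered by p ascending.
#'
#' @param result list returned by [runPipeline()].
#' @param outDir output directory.
#' @return (invisibly) the paths written.
#' @export
emitReports <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(result$mappingSummary)) {
    p <- file.path(outDir, "report_mapping.tsv")
    wide <- as.data.frame(as.list(setNames(
      result$mappingSummary$fraction,
      result$mappingSummary$category)))
    .writeTsv(wide, p); paths <- c(paths, p)
  }
  if (!is.null(result$census)) {
    p <- file.path(outDir, "report_zygosity.tsv")
    cen <- result$census
    .writeTsv(data.frame(aggressive = rownames(cen),
                         homozygous_tame = cen[, "hom"],
                         heterozygous_tame = cen[, "het"]), p)
    paths <- c(paths, p)
  }
  if (!is.null(result$de)) {
    p <- file.path(outDir, "report_expression.tsv")
    .writeTsv(result$de$table, p); paths <- c(paths, p)
  }
  invisible(paths)
}
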