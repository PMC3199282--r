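## Interchange-format writers. Internal coordinates are 0-based
## half-open; SAM and VCF emission converts to 1-based.

#' Write simulated reads as FASTQ
#'
#' @param readSet one sample's element of the [simulateReads()] result.
#' @param path output FASTQ path.
#' @return the path, invisibly.
#' @export
writeReadsFastq <- function(readSet, path) {
  Biostrings::writeXStringSet(readSet$reads, path, format = "fastq",
                              qualities = readSet$qualities)
  invisible(path)
}

#' Write error-free read placements as a SAM file
#'
#' Emits the truth alignment of each simulated read: its source gene,
#' 1-based start, strand flag and a fully-matching CIGAR of the
#' error-free length. Coordinates are on the source haplotype, which
#' matches the reference except at planted indels.
#'
#' @param origins read-origin table from [simulateReads()].
#' @param references reference set (for the SAM header).
#' @param path output SAM path.
#' @return the path, invisibly.
#' @export
writeTruthSam <- function(origins, references, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(references),
                     Biostrings::width(references)), con)
  if (nrow(origins)) {
    flag <- ifelse(origins$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                       origins$readId, flag, origins$gene,
                       origins$start, origins$trueLength), con)
  }
  invisible(path)
}

.vcfHeader <- function(sampleNames, references = NULL) {
  h <- c("##fileformat=VCFv4.2",
         "##source=VulpesTx",
         paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                "Description=\"Genotype\">"),
         paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                "Description=\"Read depth per allele\">"))
  if (!is.null(references))
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(references),
                      Biostrings::width(references)))
  c(h, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
               "INFO", "FORMAT", sampleNames), collapse = "\t"))
}

#' Write planted truth genotypes as VCF
#'
#' @param genotypes truth genotype table from [simulateIndividuals()]
#'   (1-based positions; insertions/deletions already in VCF ref/alt
#'   convention).
#' @param references reference set for contig header lines.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGenotypesVcf <- function(genotypes, references, path) {
  lines <- .vcfHeader(c("tame", "aggressive"), references)
  if (nrow(genotypes)) {
    g <- genotypes[order(genotypes$gene, genotypes$position), ,
                   drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tCLASS=%s\tGT\t%s\t%s",
      g$gene, g$position, g$ref, g$alt, g$class, g$gtTame, g$gtAggr))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write retained SNVs as a sorted VCF with per-sample allele depths
#'
#' One record per retained single-nucleotide polymorphism; indel and
#' 2-3 nt records belong in the auxiliary difference table, not here.
#'
#' @param records retained SNV records (0-based positions).
#' @param references reference set for contig header lines (optional).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSnpVcf <- function(records, path, references = NULL) {
  lines <- .vcfHeader(c("tame", "aggressive"), references)
  if (nrow(records)) {
    r <- records[records$class == "SNV", , drop = FALSE]
    r <- r[order(r$referenceId, r$position), , drop = FALSE]
    gt <- function(z) c(hom_ref = "0/0", hom_alt = "1/1", het = "0/1",
                        no_data = "./.")[z]
    lines <- c(lines, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tTIER=%s\tGT:AD\t%s:%d,%d\t%s:%d,%d",
      r$referenceId, r$position + 1L, r$ref, r$alt, r$tier,
      gt(r$zygTame), r$refT, r$altT, gt(r$zygAggr), r$refA, r$altA))
  }
  writeLines(lines, path)
  invisible(path)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
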