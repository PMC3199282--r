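## Pileup construction from classified alignments.

#' Build a per-position allele pileup split by sample
#'
#' Only alignments in the contributing categories (by default fully and
#' partially mapped; repeat-category reads are excluded) are stacked.
#' Every reference position covered by at least one alignment yields
#' per-sample allele counts. A base deleted in a read is counted as the
#' allele `"-"`; an insertion is anchored to the preceding reference
#' position by appending `"+<seq>"` to that read's allele there, so each
#' read contributes exactly one count per covered reference position.
#'
#' @param alignments data.frame from [alignReads()], with a `sample`
#'   column; rows from several samples may be combined.
#' @param references the reference [Biostrings::DNAStringSet].
#' @param includeCategories categories whose alignments contribute.
#' @return A data.frame (one row per reference, position, sample, allele)
#'   with columns referenceId, position (0-based), refAllele, sample,
#'   allele, count, ordered by reference then position.
#' @examples
#' refs <- Biostrings::DNAStringSet(c(g = "ACGTACGTACGTACGTACGTACGTACGT"))
#' reads <- Biostrings::DNAStringSet(c(r1 = "ACGTACGTACGTACGTACGT"))
#' aln <- alignReads(reads, refs, MappingThresholds(tooShortLen = 10),
#'                   sample = "tame")
#' head(buildPileup(aln, refs))
#' @export
buildPileup <- function(alignments, references,
                        includeCategories = c("fully", "partially")) {
  use <- alignments[alignments$category %in% includeCategories, ,
                    drop = FALSE]
  missing <- setdiff(unique(use$referenceId), names(references))
  if (length(missing))
    stop("alignments reference missing sequences: ",
         paste(missing, collapse = ", "), " (reads ",
         paste(head(use$readId[use$referenceId %in% missing], 3L),
               collapse = ", "), ")", call. = FALSE)
  if (nrow(use) == 0L) {
    return(data.frame(referenceId = character(), position = integer(),
                      refAllele = character(), sample = character(),
                      allele = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  refChars <- lapply(references, function(s)
    strsplit(as.character(s), "", fixed = TRUE)[[1]])
  pieces <- lapply(seq_len(nrow(use)), function(j) {
    .eventAlleles(use$events[j], use$refStart[j], use$refEnd[j],
                  use$referenceId[j], use$sample[j], refChars)
  })
  dt <- data.table::rbindlist(pieces)
  agg <- dt[, list(count = .N),
            by = c("referenceId", "position", "sample", "allele")]
  data.table::setorderv(agg, c("referenceId", "position", "sample",
                               "allele"))
  agg <- as.data.frame(agg)
  refChar <- lapply(references, as.character)
  agg$refAllele <- substring(refChar[agg$referenceId],
                             agg$position + 1L, agg$position + 1L)
  agg[, c("referenceId", "position", "refAllele", "sample", "allele",
          "count")]
}

# One alignment -> (position, allele) pairs in 0-based ref coordinates,
# reconstructed from the reference span plus the encoded events
# (M substitution, D deletion, I insertion anchored to the previous
# reference-consuming position).
.eventAlleles <- function(events, refStart, refEnd, referenceId,
                          sample_, refChars) {
  pos <- seq.int(refStart, refEnd - 1L)
  allele <- toupper(refChars[[referenceId]][pos + 1L])
  if (!is.na(events) && nzchar(events)) {
    evs <- strsplit(events, ",", fixed = TRUE)[[1]]
    kind <- substring(evs, 1L, 1L)
    body <- substring(evs, 2L)
    for (k in which(kind == "M")) {
      m <- strsplit(body[k], ":", fixed = TRUE)[[1]]
      allele[as.integer(m[1L]) - refStart + 1L] <- toupper(m[2L])
    }
    for (k in which(kind == "D"))
      allele[as.integer(body[k]) - refStart + 1L] <- "-"
    for (k in which(kind == "I")) {
      m <- strsplit(body[k], ":", fixed = TRUE)[[1]]
      at <- as.integer(m[1L]) - refStart + 1L
      if (at >= 1L && at <= length(allele))
        allele[at] <- paste0(allele[at], "+", toupper(m[2L]))
    }
  }
  data.table::data.table(referenceId = referenceId, position = pos,
                         sample = sample_, allele = allele)
}

#' Per-sample depth of a pileup
#'
#' @param pileup the long-format pileup from [buildPileup()].
#' @return data.frame referenceId, position, sample, depth (sum of allele
#'   counts, deletions included).
#' @export
pileupDepth <- function(pileup) {
  dt <- data.table::as.data.table(pileup)
  out <- dt[, list(depth = sum(count)),
            by = c("referenceId", "position", "sample")]
  as.data.frame(out)
}
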