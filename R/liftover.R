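## Synteny-based coordinate liftover and genomic-region classification.

#' Load and validate a synteny map
#'
#' A synteny map is a TSV with columns sourceChrom, sourceStart,
#' sourceEnd, targetChrom, targetStart, targetEnd, strand. Intervals are
#' 0-based half-open; source and target blocks must be the same length,
#' and source intervals must not overlap within one map.
#'
#' @param path TSV file path, or a data.frame with the same columns.
#' @return validated data.frame.
#' @export
loadSyntenyMap <- function(path) {
  map <- if (is.data.frame(path)) path else
    read.table(path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  need <- c("sourceChrom", "sourceStart", "sourceEnd", "targetChrom",
            "targetStart", "targetEnd", "strand")
  if (!all(need %in% names(map)))
    stop("synteny map needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(map$sourceEnd <= map$sourceStart))
    stop("synteny map has empty or inverted source intervals",
         call. = FALSE)
  if (any((map$sourceEnd - map$sourceStart) !=
            (map$targetEnd - map$targetStart)))
    stop("synteny blocks must have equal source and target lengths",
         call. = FALSE)
  if (!all(map$strand %in% c("+", "-")))
    stop("synteny strand must be '+' or '-'", call. = FALSE)
  for (chr in unique(map$sourceChrom)) {
    b <- map[map$sourceChrom == chr, , drop = FALSE]
    b <- b[order(b$sourceStart), , drop = FALSE]
    if (nrow(b) > 1L &&
        any(b$sourceStart[-1L] < b$sourceEnd[-nrow(b)]))
      stop("overlapping source intervals on ", chr, call. = FALSE)
  }
  map
}

#' Lift positions through a synteny map
#'
#' A position inside a block maps affinely: on the `+` strand,
#' `target = targetStart + (pos - sourceStart)`; on the `-` strand,
#' `target = targetEnd - 1 - (pos - sourceStart)`. Positions outside all
#' blocks return NA.
#'
#' @param chrom,position vectors of source coordinates (0-based).
#' @param map synteny map (see [loadSyntenyMap()]).
#' @return data.frame with chrom, position of the lifted coordinates
#'   (NA where unmapped).
#' @examples
#' map <- data.frame(sourceChrom = "c1", sourceStart = 0, sourceEnd = 100,
#'                   targetChrom = "t1", targetStart = 500,
#'                   targetEnd = 600, strand = "+")
#' liftoverPosition("c1", 10, loadSyntenyMap(map))
#' @export
liftoverPosition <- function(chrom, position, map) {
  n <- max(length(chrom), length(position))
  chrom <- rep_len(chrom, n)
  position <- rep_len(position, n)
  outChrom <- rep(NA_character_, n)
  outPos <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hit <- which(map$sourceChrom == chrom[i] &
                   map$sourceStart <= position[i] &
                   position[i] < map$sourceEnd)
    if (length(hit) == 1L) {
      b <- map[hit, ]
      off <- position[i] - b$sourceStart
      outChrom[i] <- b$targetChrom
      outPos[i] <- if (b$strand == "+") b$targetStart + off else
        b$targetEnd - 1L - off
    }
  }
  data.frame(chrom = outChrom, position = outPos,
             stringsAsFactors = FALSE)
}

#' Classify positions into genomic region types
#'
#' Each query gets exactly one label with priority coding > utr >
#' intron > repetitive > non-gene; queries on a sequence absent from the
#' annotation's universe are `unknown`.
#'
#' @param chrom,position query coordinates (position 0-based).
#' @param annotation a [GenomicRanges::GRanges] with a `type` metadata
#'   column among coding/utr/intron/repeat (1-based intervals).
#' @param knownChroms sequences considered locatable; defaults to the
#'   annotation's seqnames universe.
#' @return character vector of labels.
#' @export
classifyRegion <- function(chrom, position, annotation,
                           knownChroms = unique(as.character(
                             GenomicRanges::seqnames(annotation)))) {
  n <- max(length(chrom), length(position))
  chrom <- rep_len(chrom, n)
  position <- rep_len(position, n)
  label <- rep("unknown", n)
  known <- chrom %in% knownChroms
  label[known] <- "non-gene"
  if (any(known)) {
    q <- GenomicRanges::GRanges(chrom[known],
                                IRanges::IRanges(position[known] + 1L,
                                                 width = 1L))
    hits <- GenomicRanges::findOverlaps(q, annotation)
    if (length(hits)) {
      prio <- c(coding = 1, utr = 2, intron = 3, repeat_ = 4)
      typ <- annotation$type[S4Vectors::subjectHits(hits)]
      typ[typ == "repeat"] <- "repeat_"
      qh <- S4Vectors::queryHits(hits)
      bestLab <- tapply(prio[typ], qh, min)
      lab <- names(prio)[bestLab]
      lab <- c(coding = "coding", utr = "utr", intron = "intron",
               repeat_ = "repetitive")[lab]
      label[which(known)[as.integer(names(bestLab))]] <- lab
    }
  }
  label
}

#' Census of region labels
#'
#' @param labels output of [classifyRegion()].
#' @return data.frame of counts in the conventional order coding, intron,
#'   utr, non-gene, repetitive, unknown.
#' @export
regionCensus <- function(labels) {
  lev <- c("coding", "intron", "utr", "non-gene", "repetitive",
           "unknown")
  counts <- table(factor(labels, levels = lev))
  data.frame(region = lev, count = as.integer(counts),
             stringsAsFactors = FALSE)
}
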