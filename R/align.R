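## Read mapping and classification.
##
## The mapper is a local aligner over transcript references: a k-mer vote
## prescreen nominates candidate (reference, strand) pairs, Smith-Waterman
## (affine gaps, via Biostrings) aligns the read to each candidate, and
## the best alignment plus the flank/second-locus evidence drives the
## six-way classification: too short -> repeat -> chimeric -> fully ->
## partially -> unmapped, in that precedence order.

.alnScoring <- function() {
  list(mat = Biostrings::nucleotideSubstitutionMatrix(
         match = 2, mismatch = -3, baseOnly = TRUE),
       gapOpening = 5, gapExtension = 2)
}

.kmerIndex <- function(references, k = 12L, step = 1L) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (gi in seq_along(references)) {
    s <- as.character(references[[gi]])
    if (nchar(s) < k) next
    starts <- seq.int(1L, nchar(s) - k + 1L, by = step)
    for (km in unique(substring(s, starts, starts + k - 1L)))
      idx[[km]] <- c(idx[[km]], gi)
  }
  idx
}

# Candidate (reference, strand) pairs per read by shared k-mer votes.
.kmerCandidates <- function(reads, index, k = 12L, step = 8L,
                            nCandidates = 3L) {
  rc <- as.character(Biostrings::reverseComplement(reads))
  fw <- as.character(reads)
  lapply(seq_along(reads), function(i) {
    votes <- list()
    for (strand_ in c("+", "-")) {
      s <- if (strand_ == "+") fw[i] else rc[i]
      if (nchar(s) < k) next
      starts <- seq.int(1L, nchar(s) - k + 1L, by = step)
      hits <- unlist(lapply(substring(s, starts, starts + k - 1L),
                            function(km) index[[km]]), use.names = FALSE)
      if (length(hits)) {
        tab <- table(hits)
        votes[[strand_]] <- data.frame(
          gi = as.integer(names(tab)), strand = strand_,
          votes = as.integer(tab), stringsAsFactors = FALSE)
      }
    }
    v <- if (length(votes)) do.call(rbind, votes) else
      data.frame(gi = integer(), strand = character(),
                 votes = integer())
    v <- v[order(-v$votes), , drop = FALSE]
    # keep near-top candidates only: a genuine second locus (repeat or
    # chimera partner) shares a substantial fraction of the read's k-mers
    if (nrow(v))
      v <- v[v$votes >= max(1, 0.5 * v$votes[1L]), , drop = FALSE]
    head(v, nCandidates)
  })
}

.allCandidates <- function(nReads, nRefs) {
  all <- expand.grid(gi = seq_len(nRefs), strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  rep(list(all), nReads)
}

# Difference events of one alignment, encoded compactly:
#   M<refpos0>:<base>  substitution, D<refpos0>  deleted reference base,
#   I<refpos0>:<seq>   insertion anchored after that reference position.
# Indel events are derived arithmetically from the alignment-column
# ranges, avoiding the costly aligned-string extraction.
.indelEvents <- function(insJ, delJ, refStart1, readStart1, readSeq) {
  insCols <- unlist(Map(seq.int, IRanges::start(insJ),
                        IRanges::end(insJ)))
  delCols <- unlist(Map(seq.int, IRanges::start(delJ),
                        IRanges::end(delJ)))
  nInsBefore <- function(c) vapply(c, function(x)
    sum(insCols < x), numeric(1))
  nDelBefore <- function(c) vapply(c, function(x)
    sum(delCols < x), numeric(1))
  ev <- character(0)
  if (length(delCols)) {
    refPos0 <- (refStart1 - 1L) + (delCols - 1L - nInsBefore(delCols))
    ev <- c(ev, sprintf("D%d", as.integer(refPos0)))
  }
  if (length(insJ)) {
    s <- IRanges::start(insJ); wdt <- IRanges::width(insJ)
    anchor0 <- (refStart1 - 1L) + (s - 1L - nInsBefore(s)) - 1L
    readFrom <- readStart1 + (s - 1L - nDelBefore(s))
    seqs <- substring(readSeq, readFrom, readFrom + wdt - 1L)
    ev <- c(ev, sprintf("I%d:%s", as.integer(anchor0), seqs))
  }
  paste(ev, collapse = ",")
}

# Align (read, reference, strand) pairs, grouped so that each
# pairwiseAlignment call is vectorized over reads sharing a subject.
.alignPairs <- function(pairs, reads, readsRC, references) {
  if (nrow(pairs) == 0L) return(pairs)
  sc <- .alnScoring()
  out <- vector("list", 0L)
  key <- paste(pairs$gi, pairs$strand)
  for (grp in split(seq_len(nrow(pairs)), key)) {
    gi <- pairs$gi[grp[1L]]
    strand_ <- pairs$strand[grp[1L]]
    pat <- if (strand_ == "+") reads[pairs$ri[grp]] else
      readsRC[pairs$ri[grp]]
    pa <- Biostrings::pairwiseAlignment(
      pat, references[[gi]], type = "local",
      substitutionMatrix = sc$mat, gapOpening = sc$gapOpening,
      gapExtension = sc$gapExtension)
    ng <- length(grp)
    events <- rep("", ng)
    mt <- Biostrings::mismatchTable(pa)
    if (nrow(mt)) {
      ev <- tapply(sprintf("M%d:%s", mt$SubjectStart - 1L,
                           as.character(mt$PatternSubstring)),
                   mt$PatternId, paste, collapse = ",")
      events[as.integer(names(ev))] <- as.character(ev)
    }
    readStart <- IRanges::start(Biostrings::pattern(pa))
    refStart <- IRanges::start(Biostrings::subject(pa))
    ind <- Biostrings::indel(pa)
    insL <- Biostrings::insertion(ind)
    delL <- Biostrings::deletion(ind)
    hasIndel <- S4Vectors::elementNROWS(insL) +
      S4Vectors::elementNROWS(delL) > 0L
    for (j in which(hasIndel)) {
      iev <- .indelEvents(insL[[j]], delL[[j]], refStart[j],
                          readStart[j], as.character(pat[[j]]))
      events[j] <- if (nzchar(events[j]))
        paste(events[j], iev, sep = ",") else iev
    }
    out[[length(out) + 1L]] <- data.frame(
      ri = pairs$ri[grp], gi = gi, strand = strand_,
      score = Biostrings::score(pa),
      nMatch = Biostrings::nmatch(pa),
      alnLen = Biostrings::nchar(pa),
      readStart = readStart,
      readEnd = IRanges::end(Biostrings::pattern(pa)),
      refStart = refStart,
      refEnd = IRanges::end(Biostrings::subject(pa)),
      events = events, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Align reads to a transcript reference set and classify them
#'
#' Each read is assigned to exactly one mapping category: `too_short`
#' (shorter than `tooShortLen`), `repeats` (at least two loci whose
#' identity is within `repeatIdentityMargin` of the best and which cover
#' the read), `chimeric` (two disjoint read segments, each at least
#' `chimeraMinSegment` bases at `minIdentity`, on different references or
#' at least `chimeraMinGap` apart), `fully` (best alignment at
#' `minIdentity` covering at least `minCover` of the read), `partially`
#' (same identity over at least `partialMinCover` but less than
#' `minCover`), else `unmapped`. Identity is matches over alignment
#' columns; coverage is the aligned read span over the read length.
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param references a named [Biostrings::DNAStringSet] of transcripts.
#' @param thresholds a [MappingThresholds].
#' @param sample optional sample label attached to every row.
#' @param nCandidates candidate (reference, strand) pairs retained per
#'   read from the k-mer prescreen.
#' @param exhaustive align every read against every reference and strand,
#'   bypassing the prescreen (slow; intended for small problems and
#'   verification).
#' @return data.frame with one row per read: readId, sample, category,
#'   referenceId, strand, score, identity, coverage, readStart/readEnd
#'   (1-based, on the read in aligned orientation), refStart/refEnd
#'   (0-based half-open), nLoci, isUnique, and `events`, the encoded
#'   difference list of the best alignment (`M<pos>:<base>` substitution,
#'   `D<pos>` deletion, `I<pos>:<seq>` insertion; positions 0-based).
#' @examples
#' refs <- Biostrings::DNAStringSet(c(g1 = paste(rep("ACGT", 60),
#'                                               collapse = "")))
#' reads <- Biostrings::subseq(Biostrings::DNAStringSet(
#'   c(r1 = as.character(refs[[1]]))), 1, 100)
#' alignReads(reads, refs)[, c("readId", "category", "identity")]
#' @export
alignReads <- function(reads, references,
                       thresholds = MappingThresholds(),
                       sample = NA_character_, nCandidates = 3L,
                       exhaustive = FALSE) {
  stopifnot(is(thresholds, "MappingThresholds"))
  if (length(references) == 0L)
    stop("reference set is empty", call. = FALSE)
  n <- length(reads)
  category <- rep("unmapped", n)
  referenceId <- strand <- events <- rep(NA_character_, n)
  score <- identity <- coverage <- rep(NA_real_, n)
  readStart <- readEnd <- refStart <- refEnd <- rep(NA_integer_, n)
  nLoci <- rep(0L, n)
  assemble <- function() {
    data.frame(readId = if (is.null(names(reads)))
                 sprintf("read%06d", seq_len(n)) else names(reads),
               sample = sample, category = category,
               referenceId = referenceId, strand = strand,
               score = score, identity = identity, coverage = coverage,
               readStart = readStart, readEnd = readEnd,
               refStart = refStart, refEnd = refEnd, nLoci = nLoci,
               isUnique = category %in% c("fully", "partially"),
               events = events, stringsAsFactors = FALSE)
  }
  if (n == 0L) return(assemble())
  w <- Biostrings::width(reads)
  tooShort <- w < thresholds@tooShortLen
  category[tooShort] <- "too_short"
  alive <- which(!tooShort)
  if (!length(alive)) return(assemble())

  readsRC <- Biostrings::reverseComplement(reads)
  cand <- if (exhaustive) {
    .allCandidates(n, length(references))
  } else {
    idx <- .kmerIndex(references)
    cl <- .kmerCandidates(reads, idx, nCandidates = nCandidates)
    # reads sharing no k-mer with any reference get one exhaustive pass
    noHit <- vapply(cl, nrow, integer(1)) == 0L
    if (any(noHit & !tooShort))
      cl[noHit] <- .allCandidates(sum(noHit), length(references))
    cl
  }
  pairs <- do.call(rbind, lapply(alive, function(i)
    if (nrow(cand[[i]]))
      data.frame(ri = i, gi = cand[[i]]$gi,
                 strand = cand[[i]]$strand,
                 stringsAsFactors = FALSE)))
  aln <- .alignPairs(pairs, reads, readsRC, references)
  aln$identity <- ifelse(aln$alnLen > 0, aln$nMatch / aln$alnLen, 0)
  aln$coverage <- (aln$readEnd - aln$readStart + 1) / w[aln$ri]

  th <- thresholds
  byRead <- split(seq_len(nrow(aln)), aln$ri)
  for (iChr in names(byRead)) {
    i <- as.integer(iChr)
    rows <- aln[byRead[[iChr]], , drop = FALSE]
    best <- rows[which.max(rows$score), , drop = FALSE]
    loci <- rows[rows$identity >= best$identity -
                   th@repeatIdentityMargin &
                   rows$identity >= th@minIdentity &
                   rows$coverage >= th@minCover, , drop = FALSE]
    nl <- if (nrow(loci)) {
      lk <- paste(loci$gi, floor(loci$refStart / (2 * w[i])))
      length(unique(lk))
    } else 0L
    category[i] <- if (nl >= 2L) {
      "repeats"
    } else if (.isChimeric(i, best, reads, readsRC, references, th,
                           rows)) {
      "chimeric"
    } else if (best$identity >= th@minIdentity &&
               best$coverage >= th@minCover) {
      "fully"
    } else if (best$identity >= th@minIdentity &&
               best$coverage >= th@partialMinCover) {
      "partially"
    } else "unmapped"
    referenceId[i] <- names(references)[best$gi]
    strand[i] <- best$strand
    score[i] <- best$score
    identity[i] <- best$identity
    coverage[i] <- best$coverage
    readStart[i] <- best$readStart
    readEnd[i] <- best$readEnd
    refStart[i] <- best$refStart - 1L            # 0-based half-open
    refEnd[i] <- best$refEnd
    nLoci[i] <- max(nl, 1L)
    events[i] <- best$events
  }
  assemble()
}

# A read is chimeric when, besides the best-aligned segment (itself at
# least chimeraMinSegment bases at minIdentity), an unaligned flank of at
# least chimeraMinSegment bases aligns at minIdentity to a different
# reference, or to a locus at least chimeraMinGap away on the same one.
.isChimeric <- function(i, best, reads, readsRC, references, th, rows) {
  w <- Biostrings::width(reads)[i]
  segLen <- best$readEnd - best$readStart + 1
  if (segLen < th@chimeraMinSegment || best$identity < th@minIdentity)
    return(FALSE)
  pre <- best$readStart - 1L
  post <- w - best$readEnd
  if (max(pre, post) < th@chimeraMinSegment) return(FALSE)
  oriented <- if (best$strand == "+") reads[[i]] else readsRC[[i]]
  sc <- .alnScoring()
  flanks <- list()
  if (pre >= th@chimeraMinSegment)
    flanks$pre <- Biostrings::subseq(oriented, 1L, pre)
  if (post >= th@chimeraMinSegment)
    flanks$post <- Biostrings::subseq(oriented, best$readEnd + 1L, w)
  for (fl in flanks) {
    for (gi in seq_along(references)) {
      for (subj in list(references[[gi]],
                        Biostrings::reverseComplement(
                          references[[gi]]))) {
        pa <- Biostrings::pairwiseAlignment(
          fl, subj, type = "local", substitutionMatrix = sc$mat,
          gapOpening = sc$gapOpening, gapExtension = sc$gapExtension)
        alnLen <- Biostrings::nchar(pa)
        idy <- if (alnLen > 0) Biostrings::nmatch(pa) / alnLen else 0
        span <- IRanges::width(Biostrings::pattern(pa))
        if (idy >= th@minIdentity && span >= th@chimeraMinSegment) {
          if (gi != best$gi) return(TRUE)
          gap <- abs(IRanges::start(Biostrings::subject(pa)) -
                       best$refStart)
          if (gap >= th@chimeraMinGap) return(TRUE)
        }
      }
    }
  }
  FALSE
}

#' Summarize mapping categories
#'
#' Tabulates read counts and fractions across the six mapping categories
#' in the conventional order: fully mapped, partially mapped, unmapped,
#' repeats, chimeric, too short to map. Fractions are computed over the
#' total read count and sum to 1.
#'
#' @param alignments the data.frame from [alignReads()] (rows from several
#'   samples may be combined).
#' @return data.frame with category, count, fraction.
#' @examples
#' df <- data.frame(category = c("fully", "fully", "unmapped"))
#' classifyReads(df)
#' @export
classifyReads <- function(alignments) {
  lev <- c("fully", "partially", "unmapped", "repeats", "chimeric",
           "too_short")
  stopifnot(all(alignments$category %in% lev))
  counts <- table(factor(alignments$category, levels = lev))
  data.frame(category = lev, count = as.integer(counts),
             fraction = as.numeric(counts) / max(1L, nrow(alignments)),
             stringsAsFactors = FALSE)
}
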