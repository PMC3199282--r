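## Candidate difference enumeration, fixed-vs-polymorphic partition,
## tiered high-confidence SNP filters and zygosity classification.

.emptyDifferenceTable <- function() {
  data.frame(referenceId = character(), position = integer(),
             ref = character(), alt = character(), class = character(),
             refT = integer(), altT = integer(), refA = integer(),
             altA = integer(), depthT = integer(), depthA = integer(),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate differences from a pileup
#'
#' Every pileup column where at least two reads (pooled over samples)
#' support the same non-reference allele yields one candidate record with
#' per-sample allele counts. Base substitutions yield SNV records; the
#' deletion symbol and anchored insertions yield indel records. Adjacent
#' runs of two or three SNV columns whose per-sample counts are identical
#' (the signature of one non-reference haplotype carrying them all) are
#' merged into a single 2-3 nucleotide (MNP2/MNP3) record.
#'
#' @param pileup long-format pileup from [buildPileup()], ordered by
#'   reference and position.
#' @param samples the two sample labels, first mapped to the `T` count
#'   columns, second to the `A` columns.
#' @param minAltReads pooled read support required for a candidate.
#' @return data.frame: referenceId, position (0-based), ref, alt, class
#'   (SNV/indel/MNP2/MNP3), refT, altT, refA, altA, depthT, depthA.
#' @export
enumerateDifferences <- function(pileup,
                                 samples = c("tame", "aggressive"),
                                 minAltReads = 2L) {
  if (nrow(pileup) == 0L) return(.emptyDifferenceTable())
  dt <- data.table::as.data.table(pileup)
  ord <- dt[, list(ok = !is.unsorted(position)), by = "referenceId"]
  if (any(!ord$ok))
    stop("pileup positions are not ordered within ",
         paste(ord$referenceId[!ord$ok], collapse = ", "),
         call. = FALSE)
  dt[, base := substring(allele, 1L, 1L)]
  dt[, insSeq := ifelse(nchar(allele) > 1L, substring(allele, 3L), "")]

  # columns made purely of reference-matching reads cannot yield a
  # candidate; drop them before the per-column pass
  dt[, anyNonRef := any(allele != refAllele),
     by = c("referenceId", "position")]
  dt <- dt[anyNonRef == TRUE]
  if (nrow(dt) == 0L) return(.emptyDifferenceTable())

  recs <- lapply(split(dt, by = c("referenceId", "position"),
                       sorted = TRUE),
                 .columnCandidate, samples = samples,
                 minAltReads = minAltReads)
  recs <- data.table::rbindlist(recs[!vapply(recs, is.null,
                                             logical(1))])
  if (is.null(recs) || nrow(recs) == 0L)
    return(.emptyDifferenceTable())
  out <- as.data.frame(recs)
  .mergeMnpRuns(out)
}

.columnCandidate <- function(col, samples, minAltReads) {
  refAllele <- col$refAllele[1L]
  depths <- vapply(samples, function(s) sum(col$count[col$sample == s]),
                   numeric(1))
  # base-level pooled counts (insertion-carrying reads still support
  # their base at this column)
  baseTot <- tapply(col$count, col$base, sum)
  cand <- data.frame(alt = character(), class = character(),
                     n = numeric())
  nonRef <- setdiff(names(baseTot), c(refAllele, "N"))
  if (length(nonRef)) {
    keep <- baseTot[nonRef] >= minAltReads
    if (any(keep))
      cand <- rbind(cand, data.frame(
        alt = nonRef[keep],
        class = ifelse(nonRef[keep] == "-", "indel", "SNV"),
        n = as.numeric(baseTot[nonRef][keep])))
  }
  insRows <- col[col$insSeq != "", ]
  if (nrow(insRows)) {
    insTot <- tapply(insRows$count, insRows$insSeq, sum)
    keep <- insTot >= minAltReads
    if (any(keep))
      cand <- rbind(cand, data.frame(
        alt = paste0(refAllele, "+", names(insTot)[keep]),
        class = "indel", n = as.numeric(insTot[keep])))
  }
  if (nrow(cand) == 0L) return(NULL)
  best <- cand[which.max(cand$n), ]
  isIns <- best$class == "indel" && grepl("+", best$alt, fixed = TRUE)
  insPart <- if (isIns) sub("^.\\+", "", best$alt) else ""
  refCount <- vapply(samples, function(s)
    sum(col$count[col$sample == s & col$base == refAllele &
                    col$insSeq == ""]), numeric(1))
  altCount <- vapply(samples, function(s) {
    if (isIns) sum(col$count[col$sample == s & col$insSeq == insPart])
    else sum(col$count[col$sample == s & col$base == best$alt &
                         col$insSeq == ""])
  }, numeric(1))
  data.table::data.table(
    referenceId = col$referenceId[1L], position = col$position[1L],
    ref = refAllele, alt = best$alt, class = best$class,
    refT = as.integer(refCount[1L]), altT = as.integer(altCount[1L]),
    refA = as.integer(refCount[2L]), altA = as.integer(altCount[2L]),
    depthT = as.integer(depths[1L]), depthA = as.integer(depths[2L]))
}

# Merge adjacent co-varying SNV columns (runs of 2-3 with identical
# per-sample counts) into MNP2/MNP3 records. Longer runs are left as SNVs.
.mergeMnpRuns <- function(recs) {
  recs <- recs[order(recs$referenceId, recs$position), , drop = FALSE]
  isSnv <- recs$class == "SNV"
  sig <- paste(recs$referenceId, recs$refT, recs$altT, recs$refA,
               recs$altA)
  newRun <- !(isSnv & c(FALSE, isSnv[-length(isSnv)]) &
                c(FALSE, diff(recs$position) == 1L) &
                c(FALSE, sig[-1L] == sig[-length(sig)]))
  runId <- cumsum(newRun)
  out <- lapply(split(seq_len(nrow(recs)), runId), function(ix) {
    if (length(ix) %in% c(2L, 3L) && all(recs$class[ix] == "SNV")) {
      r <- recs[ix[1L], , drop = FALSE]
      r$ref <- paste(recs$ref[ix], collapse = "")
      r$alt <- paste(recs$alt[ix], collapse = "")
      r$class <- paste0("MNP", length(ix))
      r$refT <- min(recs$refT[ix]); r$refA <- min(recs$refA[ix])
      r$depthT <- min(recs$depthT[ix]); r$depthA <- min(recs$depthA[ix])
      r
    } else recs[ix, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Partition candidate differences into fixed differences vs polymorphisms
#'
#' Pooling reads from both individuals, a record whose minor allele
#' (reference-matching or alternate, whichever is rarer) falls at or
#' below the error floor is either a species-level fixed difference (the
#' alternate allele reaches the consensus fraction, default 95%, of all
#' reads) or excluded as likely sequencing error. Records where both
#' alleles clear the error floor are within-species polymorphisms.
#'
#' @param records difference table from [enumerateDifferences()].
#' @param config a [SnpFilterConfig].
#' @return the table with a `status` column added: `fixed_difference`,
#'   `polymorphism`, or `excluded_error_floor`.
#' @export
partitionDifferences <- function(records, config = SnpFilterConfig()) {
  stopifnot(is(config, "SnpFilterConfig"))
  if (nrow(records) == 0L) {
    records$status <- character(0)
    return(records)
  }
  nRef <- records$refT + records$refA
  nAlt <- records$altT + records$altA
  depth <- records$depthT + records$depthA
  stopifnot(all(depth >= 1))
  fRef <- nRef / depth
  fAlt <- nAlt / depth
  minor <- pmin(fRef, fAlt)
  records$status <- ifelse(
    minor <= config@errorFloorHigh,
    ifelse(fAlt >= config@fixedDiffConsensus, "fixed_difference",
           "excluded_error_floor"),
    "polymorphism")
  records
}

# Within-sample allele evaluation shared by the tier filter and zygosity
# calls: fractions are over reference + alternate reads in that sample.
.sampleAlleleCounts <- function(records, which) {
  if (which == "T") cbind(ref = records$refT, alt = records$altT)
  else cbind(ref = records$refA, alt = records$altA)
}

.passes25 <- function(counts, minMinorFrac, errorFloor = 0) {
  tot <- counts[, "ref"] + counts[, "alt"]
  ok <- rep(TRUE, nrow(counts))
  seen <- tot > 0
  frac <- counts / pmax(tot, 1L)
  # every observed allele must reach the minor-allele floor; alleles at
  # or below the per-sample error floor are treated as sequencing error
  # and disregarded, mirroring the pooled error-floor rule
  observed <- function(a) counts[, a] > 0 &
    frac[, a] > errorFloor + 1e-12
  bad <- seen & ((observed("ref") &
                    frac[, "ref"] < minMinorFrac - 1e-12) |
                 (observed("alt") &
                    frac[, "alt"] < minMinorFrac - 1e-12))
  ok & !bad
}

#' Apply the tiered high-confidence SNP filters
#'
#' Operates on polymorphic SNV records ([partitionDifferences()] status
#' `polymorphism`); indel and 2-3 nt records are marked
#' `excluded_class`. Tier A: the minor allele reaches `minMinorFrac` of
#' reads in every sample where both alleles are observed (an allele at
#' or below the per-sample error floor counts as unobserved), and some
#' individual shows more than `minReadsPerAllele` reads for each allele
#' it carries. Tier B: the same, with exactly `minReadsPerAllele` reads
#' per allele in that individual. Tier C: at least `minReadsPerAllele`
#' minor-allele reads summed over both individuals. Records failing all
#' tiers get tier `"none"` and are not retained.
#'
#' @param records the partitioned difference table.
#' @param config a [SnpFilterConfig].
#' @return the table with `tier` ("A", "B", "C", "none") and `retained`
#'   (logical) columns added; `status` becomes `excluded_class` for
#'   non-SNV polymorphisms.
#' @export
filterHighConfidence <- function(records, config = SnpFilterConfig()) {
  stopifnot(is(config, "SnpFilterConfig"))
  records$tier <- rep("none", nrow(records))
  records$retained <- rep(FALSE, nrow(records))
  if (nrow(records) == 0L) return(records)
  poly <- records$status == "polymorphism"
  records$status[poly & records$class != "SNV"] <- "excluded_class"
  cand <- which(records$status == "polymorphism" &
                  records$class == "SNV")
  if (!length(cand)) return(records)
  sub <- records[cand, , drop = FALSE]
  cT <- .sampleAlleleCounts(sub, "T")
  cA <- .sampleAlleleCounts(sub, "A")
  rule25 <- .passes25(cT, config@minMinorFrac, config@errorFloorHigh) &
    .passes25(cA, config@minMinorFrac, config@errorFloorHigh)
  m <- config@minReadsPerAllele
  allAbove <- function(cc, test) {
    tot <- cc[, "ref"] + cc[, "alt"]
    seen <- tot > 0
    okRef <- cc[, "ref"] == 0 | test(cc[, "ref"])
    okAlt <- cc[, "alt"] == 0 | test(cc[, "alt"])
    seen & okRef & okAlt
  }
  depthA_gt <- allAbove(cT, function(x) x > m) |
    allAbove(cA, function(x) x > m)
  exact3 <- function(cc) {
    tot <- cc[, "ref"] + cc[, "alt"]
    seen <- tot > 0
    okRef <- cc[, "ref"] == 0 | cc[, "ref"] == m
    okAlt <- cc[, "alt"] == 0 | cc[, "alt"] == m
    seen & okRef & okAlt
  }
  depthB <- exact3(cT) | exact3(cA)
  minorPooled <- pmin(sub$refT + sub$refA, sub$altT + sub$altA)
  tier <- ifelse(rule25 & depthA_gt, "A",
          ifelse(rule25 & depthB, "B",
          ifelse(minorPooled >= m, "C", "none")))
  records$tier[cand] <- tier
  records$retained[cand] <- tier != "none"
  records
}

#' Classify per-sample zygosity and the joint zygosity category
#'
#' A sample is called heterozygous at a retained SNP when both alleles
#' pass the same retention thresholds within that sample (fraction at
#' least `minMinorFrac` of the sample's ref+alt reads and at least
#' `minReadsPerAllele` reads); otherwise the sample is homozygous for its
#' modal allele. A sample with zero depth is `no_data` and the record is
#' excluded from the joint census.
#'
#' @param records a difference table (typically retained SNVs).
#' @param config a [SnpFilterConfig].
#' @return the table with `zygTame`, `zygAggr` (hom_ref / hom_alt / het /
#'   no_data) and `category` (homT.homA, hetT.homA, homT.hetA, hetT.hetA,
#'   or NA when either sample lacks data) columns added.
#' @export
classifyZygosity <- function(records, config = SnpFilterConfig()) {
  stopifnot(is(config, "SnpFilterConfig"))
  call1 <- function(ref, alt) {
    tot <- ref + alt
    if (tot == 0L) return("no_data")
    m <- config@minReadsPerAllele
    f <- config@minMinorFrac
    hetOk <- ref >= m && alt >= m && ref / tot >= f - 1e-12 &&
      alt / tot >= f - 1e-12
    if (hetOk) "het" else if (alt > ref) "hom_alt" else "hom_ref"
  }
  zT <- mapply(call1, records$refT, records$altT)
  zA <- mapply(call1, records$refA, records$altA)
  records$zygTame <- as.character(zT)
  records$zygAggr <- as.character(zA)
  hz <- function(z) ifelse(z == "het", "het",
                           ifelse(z == "no_data", NA, "hom"))
  ht <- hz(records$zygTame); ha <- hz(records$zygAggr)
  records$category <- ifelse(
    is.na(ht) | is.na(ha), NA_character_,
    paste0(ifelse(ht == "hom", "homT", "hetT"), ".",
           ifelse(ha == "hom", "homA", "hetA")))
  records
}

#' Joint zygosity census (2x2)
#'
#' Tabulates retained SNPs into the four informativeness cells: each axis
#' is whether the tame or aggressive individual is homozygous or
#' heterozygous. Records lacking a call in either sample are excluded.
#'
#' @param records output of [classifyZygosity()].
#' @return a 2x2 integer matrix, rows = aggressive (hom, het), columns =
#'   tame (hom, het).
#' @export
zygosityCensus <- function(records) {
  cells <- c("homT.homA", "hetT.homA", "homT.hetA", "hetT.hetA")
  counts <- vapply(cells, function(cl)
    sum(!is.na(records$category) & records$category == cl), integer(1))
  matrix(c(counts["homT.homA"], counts["hetT.homA"],
           counts["homT.hetA"], counts["hetT.hetA"]),
         nrow = 2L, byrow = TRUE,
         dimnames = list(aggressive = c("hom", "het"),
                         tame = c("hom", "het")))
}

#' Filter apparently heterozygous X-linked SNPs in male samples
#'
#' Both sequenced individuals are male, so a true X-linked site outside
#' the pseudoautosomal region (PAR) must be hemizygous; apparent
#' heterozygosity there is an artifact. Records assigned to the X outside
#' the PAR intervals and called heterozygous in either individual get
#' status `excluded_x_het`; PAR records are untouched. Records without a
#' chromosome assignment pass with a warning flag (`xFilterUnknown`).
#'
#' @param records output of [classifyZygosity()].
#' @param chromAssignment named character vector mapping referenceId to
#'   chromosome; or NULL to use a `chrom` column already on the records.
#' @param parIntervals a [GenomicRanges::GRanges] of PAR intervals in
#'   chromosome coordinates (1-based).
#' @param xChrom name of the X chromosome in the assignment.
#' @return the table with status updated and an `xFilterUnknown` flag.
#' @export
filterXHeterozygotes <- function(records, chromAssignment = NULL,
                                 parIntervals = GenomicRanges::GRanges(),
                                 xChrom = "chrX") {
  if (nrow(records) == 0L) {
    records$xFilterUnknown <- logical(0)
    return(records)
  }
  chrom <- if (!is.null(chromAssignment)) {
    unname(chromAssignment[records$referenceId])
  } else records$chrom
  pos <- if ("chromPos" %in% names(records)) records$chromPos else
    records$position
  records$xFilterUnknown <- is.na(chrom)
  if (any(records$xFilterUnknown))
    warning(sum(records$xFilterUnknown),
            " records lack a chromosome assignment; X filter not applied",
            call. = FALSE)
  onX <- !is.na(chrom) & chrom == xChrom
  inPar <- rep(FALSE, nrow(records))
  if (length(parIntervals) && any(onX)) {
    q <- GenomicRanges::GRanges(chrom[onX],
                                IRanges::IRanges(pos[onX] + 1L,
                                                 width = 1L))
    inPar[onX] <- IRanges::overlapsAny(q, parIntervals)
  }
  het <- records$zygTame == "het" | records$zygAggr == "het"
  drop <- onX & !inPar & het
  records$status[drop] <- "excluded_x_het"
  records$retained[drop] <- FALSE
  records
}

#' Merge genome-derived and contig-derived SNP sets
#'
#' Contig-derived records are lifted to genome coordinates through a
#' contig-to-genome synteny map (unliftable records are kept and flagged
#' `source = "contig_ref"`). Records identical in (chromosome, position,
#' alleles) are merged into one with `source = "both"`, keeping the
#' counts of the deeper-evidence source (the genome-derived record wins
#' ties). Same-position records with different alleles are both kept and
#' conflict-flagged. Output is sorted by chromosome and position.
#'
#' @param genomeDerived,contigDerived difference tables; genome-derived
#'   records use `chrom`/`chromPos` columns if present, else
#'   referenceId/position.
#' @param contigMap synteny map (see [loadSyntenyMap()]) lifting contig
#'   coordinates to the genome, or NULL if contig records are already in
#'   genome coordinates.
#' @return combined table with `source` and `conflict` columns.
#' @export
mergeSnpSets <- function(genomeDerived, contigDerived,
                         contigMap = NULL) {
  norm <- function(df, src) {
    if (nrow(df) == 0L) {
      df$chrom <- character(0); df$chromPos <- integer(0)
      df$source <- character(0)
      return(df)
    }
    if (!"chrom" %in% names(df)) df$chrom <- df$referenceId
    if (!"chromPos" %in% names(df)) df$chromPos <- df$position
    df$source <- src
    df
  }
  g <- norm(genomeDerived, "genome_ref")
  ct <- norm(contigDerived, "contig_ref")
  if (!is.null(contigMap) && nrow(ct)) {
    lifted <- liftoverPosition(ct$chrom, ct$chromPos, contigMap)
    ok <- !is.na(lifted$chrom)
    ct$chrom[ok] <- lifted$chrom[ok]
    ct$chromPos[ok] <- lifted$position[ok]
  }
  both <- rbind(g, ct)
  if (nrow(both) == 0L) {
    both$conflict <- logical(0)
    return(both)
  }
  key <- paste(both$chrom, both$chromPos, both$ref, both$alt,
               sep = "\r")
  depth <- both$depthT + both$depthA
  pref <- ifelse(both$source == "genome_ref", 1L, 0L)
  ord <- order(key, -depth, -pref)
  both <- both[ord, , drop = FALSE]
  key <- key[ord]
  dup <- duplicated(key)
  merged <- both[!dup, , drop = FALSE]
  seenBoth <- key[!dup] %in% key[dup]
  merged$source[seenBoth] <- "both"
  posKey <- paste(merged$chrom, merged$chromPos, sep = "\r")
  merged$conflict <- posKey %in% posKey[duplicated(posKey)]
  merged <- merged[order(merged$chrom, merged$chromPos), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}
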