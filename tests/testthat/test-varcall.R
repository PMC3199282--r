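# Helpers to build pileup columns and difference records compactly.
pileupCol <- function(ref, pos, refAllele, tame = c(), aggr = c()) {
  rows <- list()
  for (s in c("tame", "aggressive")) {
    al <- if (s == "tame") tame else aggr
    if (length(al))
      rows[[s]] <- data.frame(referenceId = ref, position = pos,
                              refAllele = refAllele, sample = s,
                              allele = names(al),
                              count = as.integer(al),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

rec <- function(refT, altT, refA, altA, class = "SNV",
                status = "polymorphism", ref = "G", alt = "A",
                pos = 10L, refId = "g1") {
  data.frame(referenceId = refId, position = pos, ref = ref, alt = alt,
             class = class, refT = refT, altT = altT, refA = refA,
             altA = altA, depthT = refT + altT, depthA = refA + altA,
             status = status, stringsAsFactors = FALSE)
}

test_that("difference enumeration finds supported alternates only", {
  # fourteen reads all carrying A over a reference G
  pu <- pileupCol("g1", 7L, "G", tame = c(A = 8), aggr = c(A = 6))
  d <- enumerateDifferences(pu)
  expect_equal(nrow(d), 1L)
  expect_equal(d$alt, "A")
  expect_equal(d$class, "SNV")
  expect_equal(d$altT + d$altA, 14L)

  # a column matching the reference yields nothing
  puRef <- pileupCol("g1", 3L, "C", tame = c(C = 10), aggr = c(C = 4))
  expect_equal(nrow(enumerateDifferences(puRef)), 0L)

  # a single supporting read is below the two-read floor
  pu1 <- pileupCol("g1", 5L, "T", tame = c(T = 9, G = 1))
  expect_equal(nrow(enumerateDifferences(pu1)), 0L)
})

test_that("unordered pileup input is rejected", {
  pu <- rbind(pileupCol("g1", 9L, "G", tame = c(A = 3)),
              pileupCol("g1", 2L, "C", tame = c(T = 3)))
  expect_error(enumerateDifferences(pu), "ordered")
})

test_that("co-varying adjacent columns merge into one MNP record", {
  pu <- rbind(
    pileupCol("g1", 10L, "G", tame = c(A = 5, G = 4),
              aggr = c(G = 6)),
    pileupCol("g1", 11L, "C", tame = c(T = 5, C = 4),
              aggr = c(C = 6)),
    pileupCol("g1", 12L, "G", tame = c(C = 5, G = 4),
              aggr = c(G = 6)))
  d <- enumerateDifferences(pu)
  expect_equal(nrow(d), 1L)
  expect_equal(d$class, "MNP3")
  expect_equal(d$ref, "GCG")
  expect_equal(d$alt, "ATC")
  expect_equal(d$altT, 5L)

  # the naive per-column oracle: three SNV candidates with identical
  # per-sample counts and consecutive positions collapse to one span
  perColumn <- lapply(10:12, function(p)
    enumerateDifferences(pu[pu$position == p, ]))
  expect_true(all(vapply(perColumn, nrow, integer(1)) == 1L))
  counts <- t(vapply(perColumn, function(x)
    c(x$refT, x$altT, x$refA, x$altA), integer(4)))
  expect_true(all(apply(counts, 2, function(v) length(unique(v)) == 1)))

  # differing counts must not merge
  pu2 <- rbind(
    pileupCol("g1", 10L, "G", tame = c(A = 5, G = 4)),
    pileupCol("g1", 11L, "C", tame = c(T = 3, C = 6)))
  expect_equal(sort(enumerateDifferences(pu2)$class),
               c("SNV", "SNV"))
})

test_that("fixed differences and polymorphisms partition correctly", {
  # all reads alternate: a species-level fixed difference
  d <- partitionDifferences(rec(0, 12, 0, 8))
  expect_equal(d$status, "fixed_difference")

  # a 3% second allele is within the error floor and ignored
  d2 <- partitionDifferences(
    data.frame(referenceId = "g1", position = 5L, ref = "G", alt = "A",
               class = "SNV", refT = 2, altT = 50, refA = 1, altA = 47,
               depthT = 52, depthA = 48, stringsAsFactors = FALSE))
  expect_equal(d2$status, "fixed_difference")

  # balanced alleles across samples: polymorphism
  d3 <- partitionDifferences(rec(5, 5, 5, 5))
  expect_equal(d3$status, "polymorphism")

  # a 4% minor allele that never reaches consensus is excluded
  d4 <- partitionDifferences(rec(48, 2, 48, 2))
  expect_equal(d4$status, "excluded_error_floor")
})

test_that("tier assignment matches the spec examples", {
  cfg <- SnpFilterConfig()
  # T 5/5, A 6/0: minor at 50% in T, aggressive individual has > 3
  # reads for its single allele -> tier A
  a <- filterHighConfidence(rec(5, 5, 6, 0), cfg)
  expect_equal(a$tier, "A")
  # T 3/3, A absent -> exactly three reads per allele: tier B
  b <- filterHighConfidence(rec(3, 3, 0, 0), cfg)
  expect_equal(b$tier, "B")
  # alternate below 25% everywhere but 3 reads pooled -> tier C
  cc <- filterHighConfidence(rec(8, 2, 8, 1), cfg)
  expect_equal(cc$tier, "C")
  # non-SNV polymorphisms are excluded by class
  ind <- filterHighConfidence(rec(5, 5, 6, 0, class = "indel"), cfg)
  expect_equal(ind$status, "excluded_class")
  expect_equal(ind$tier, "none")
})

test_that("tier rules agree with an exhaustive rule oracle on the
           count grid", {
  # on this grid every nonzero within-sample fraction exceeds the 5%
  # error floor (min 1/12), so the oracle can omit the floor clause
  cfg <- SnpFilterConfig()
  grid <- expand.grid(refT = 0:6, altT = 0:6, refA = 0:6, altA = 0:6)
  grid <- grid[grid$refT + grid$altT + grid$refA + grid$altA > 0, ]
  recs <- rec(grid$refT, grid$altT, grid$refA, grid$altA)
  recs$position <- seq_len(nrow(recs))
  got <- filterHighConfidence(recs, cfg)$tier
  want <- mapply(oracleTier, grid$refT, grid$altT, grid$refA,
                 grid$altA)
  expect_equal(got, unname(want))
})

test_that("tiers A and B are disjoint and within the 25% rule", {
  set.seed(61)
  n <- 400
  recs <- rec(sample(0:12, n, TRUE), sample(0:12, n, TRUE),
              sample(0:12, n, TRUE), sample(0:12, n, TRUE))
  recs$position <- seq_len(n)
  out <- filterHighConfidence(recs, SnpFilterConfig())
  expect_true(all(out$tier %in% c("A", "B", "C", "none")))
  ab <- out[out$tier %in% c("A", "B"), ]
  ok25 <- function(r, a) {
    tot <- r + a
    tot == 0 | ((r == 0 | r / pmax(tot, 1) >= 0.25) &
                  (a == 0 | a / pmax(tot, 1) >= 0.25))
  }
  expect_true(all(ok25(ab$refT, ab$altT) & ok25(ab$refA, ab$altA)))
})

test_that("raising thresholds never grows the retained set", {
  set.seed(71)
  n <- 300
  recs <- rec(sample(0:15, n, TRUE), sample(0:15, n, TRUE),
              sample(0:15, n, TRUE), sample(0:15, n, TRUE))
  recs$position <- seq_len(n)
  base <- filterHighConfidence(recs, SnpFilterConfig())
  stricterDepth <- filterHighConfidence(
    recs, SnpFilterConfig(minReadsPerAllele = 5))
  stricterFrac <- filterHighConfidence(
    recs, SnpFilterConfig(minMinorFrac = 0.35))
  expect_true(all(stricterDepth$retained <= base$retained |
                    stricterDepth$tier == "C"))
  expect_lte(sum(stricterFrac$retained & stricterFrac$tier != "C"),
             sum(base$retained & base$tier != "C"))
  expect_lte(sum(stricterDepth$retained), sum(base$retained))
})

test_that("zygosity calls and the joint census follow the thresholds", {
  cfg <- SnpFilterConfig()
  hh <- classifyZygosity(rec(0, 10, 10, 0), cfg)
  expect_equal(hh$zygTame, "hom_alt")
  expect_equal(hh$zygAggr, "hom_ref")
  expect_equal(hh$category, "homT.homA")

  het <- classifyZygosity(rec(6, 6, 7, 5), cfg)
  expect_equal(het$zygTame, "het")
  expect_equal(het$zygAggr, "het")
  expect_equal(het$category, "hetT.hetA")

  nd <- classifyZygosity(rec(0, 0, 4, 4), cfg)
  expect_equal(nd$zygTame, "no_data")
  expect_true(is.na(nd$category))

  # hand-filled 2x2 for a 12-record fixture:
  # 4 hom/hom, 3 het(T)/hom, 3 hom/het(A), 2 het/het
  mk <- function(rT, aT, rA, aA) rec(rT, aT, rA, aA)
  fix <- do.call(rbind, c(
    replicate(4, mk(0, 8, 8, 0), simplify = FALSE),
    replicate(3, mk(5, 5, 9, 0), simplify = FALSE),
    replicate(3, mk(8, 0, 4, 6), simplify = FALSE),
    replicate(2, mk(5, 6, 6, 5), simplify = FALSE)))
  fix$position <- seq_len(nrow(fix))
  cen <- zygosityCensus(classifyZygosity(fix, cfg))
  expect_equal(unname(cen["hom", "hom"]), 4L)
  expect_equal(unname(cen["hom", "het"]), 3L)
  expect_equal(unname(cen["het", "hom"]), 3L)
  expect_equal(unname(cen["het", "het"]), 2L)
  expect_equal(sum(cen), 12L)
})

test_that("the X filter drops male heterozygotes outside the PAR", {
  cfg <- SnpFilterConfig()
  recs <- do.call(rbind, list(
    rec(5, 5, 9, 0, refId = "gX1", pos = 100L),   # het on X
    rec(0, 9, 9, 0, refId = "gX2", pos = 200L),   # hom-hom on X
    rec(5, 5, 9, 0, refId = "gXp", pos = 50L),    # het inside PAR
    rec(5, 5, 9, 0, refId = "gAuto", pos = 10L))) # het autosomal
  recs$retained <- TRUE
  recs <- classifyZygosity(recs, cfg)
  chromOf <- c(gX1 = "chrX", gX2 = "chrX", gXp = "chrX",
               gAuto = "chr5")
  par <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 60))
  out <- filterXHeterozygotes(recs, chromOf, par)
  expect_equal(out$status,
               c("excluded_x_het", "polymorphism", "polymorphism",
                 "polymorphism"))
  expect_false(out$retained[1])
  expect_true(all(out$retained[2:4]))

  # missing assignment: record passes, flagged
  out2 <- suppressWarnings(
    filterXHeterozygotes(recs, chromOf[-1], par))
  expect_true(out2$xFilterUnknown[1])
  expect_equal(out2$status[1], "polymorphism")
})

test_that("merging SNP sets dedups, prefers deeper evidence and sorts", {
  g <- rec(10, 10, 5, 5, pos = 100L, refId = "chr1")
  ct <- rec(3, 3, 3, 3, pos = 100L, refId = "chr1")
  m <- mergeSnpSets(g, ct)
  expect_equal(nrow(m), 1L)
  expect_equal(m$source, "both")
  expect_equal(m$refT, 10L)    # deeper (genome) evidence kept

  g3 <- do.call(rbind, lapply(c(10L, 30L, 50L), function(p)
    rec(4, 4, 4, 4, pos = p, refId = "chr2")))
  c4 <- do.call(rbind, lapply(c(70L, 90L, 110L, 130L), function(p)
    rec(4, 4, 4, 4, pos = p, refId = "chr2")))
  expect_equal(nrow(mergeSnpSets(g3, c4)), 7L)

  # 2 duplicates among 10 -> 8, equal to the hash-dedup oracle
  set.seed(41)
  ten <- do.call(rbind, lapply(c(1, 2, 3, 4, 5, 6, 7, 8, 1, 4),
                               function(p) rec(4, 4, 4, 4,
                                               pos = as.integer(p),
                                               refId = "chr3")))
  half <- ten[1:5, ]; rest <- ten[6:10, ]
  m10 <- mergeSnpSets(half, rest)
  expect_equal(nrow(m10), 8L)
  expect_setequal(paste(m10$chrom, m10$chromPos, m10$ref, m10$alt,
                        sep = "\r"),
                  oracleDedupKeys(transform(ten, chrom = referenceId,
                                            chromPos = position)))

  # idempotence: merge(S, S) = dedup(S)
  mSS <- mergeSnpSets(ten, ten)
  expect_equal(nrow(mSS), 8L)

  # allele conflicts at one position are kept and flagged
  alt2 <- rec(4, 4, 4, 4, pos = 100L, refId = "chr1", alt = "T")
  conf <- mergeSnpSets(g, alt2)
  expect_equal(nrow(conf), 2L)
  expect_true(all(conf$conflict))
})

test_that("contig records are lifted into genome coordinates on merge", {
  map <- loadSyntenyMap(data.frame(
    sourceChrom = "contig1", sourceStart = 0L, sourceEnd = 200L,
    targetChrom = "chr7", targetStart = 1000L, targetEnd = 1200L,
    strand = "+", stringsAsFactors = FALSE))
  g <- rec(8, 8, 8, 8, pos = 1050L, refId = "chr7")
  ct <- rec(2, 2, 2, 2, pos = 50L, refId = "contig1")
  m <- mergeSnpSets(g, ct, contigMap = map)
  expect_equal(nrow(m), 1L)
  expect_equal(m$source, "both")

  orphan <- rec(2, 2, 2, 2, pos = 500L, refId = "contig1")
  m2 <- mergeSnpSets(g, orphan, contigMap = map)
  expect_equal(nrow(m2), 2L)
  expect_true("contig_ref" %in% m2$source)
})
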