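test_that("degenerate sizes and determinism of the transcriptome", {
  cfg <- SimConfig(nGenes = 1L, seed = 7)
  ref <- simulateTranscriptome(cfg, forceLength = 100)
  expect_length(ref$sequences, 1L)
  expect_equal(Biostrings::width(ref$sequences), 100L)
  expect_true(all(strsplit(as.character(ref$sequences[[1]]),
                           "")[[1]] %in% c("A", "C", "G", "T")))

  cfg2 <- SimConfig(nGenes = 5L, seed = 7)
  a <- simulateTranscriptome(cfg2)
  b <- simulateTranscriptome(cfg2)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
})

test_that("uniform base model keeps GC near one half", {
  cfg <- SimConfig(nGenes = 50L, seed = 3)
  ref <- simulateTranscriptome(cfg)
  freq <- Biostrings::alphabetFrequency(ref$sequences, collapse = TRUE)
  gc <- sum(freq[c("C", "G")]) / sum(freq[c("A", "C", "G", "T")])
  expect_gt(gc, 0.45)
  expect_lt(gc, 0.55)
})

test_that("invalid configurations are rejected", {
  expect_error(SimConfig(nGenes = 0), "nGenes")
  expect_error(SimConfig(zygosityMix = c(0.5, 0.5, 0, 0.1)),
               "zygosityMix")
  expect_error(SimConfig(subErrorRate = 2), "subErrorRate")
  expect_error(SimConfig(deFold = 0), "deFold")
  expect_error(SimConfig(readLengthMin = 0), "readLengthMin")
})

test_that("zero variant rate yields haplotypes equal to the reference", {
  cfg <- SimConfig(nGenes = 3L, snpRate = 0, seed = 5)
  ref <- simulateTranscriptome(cfg)
  ind <- simulateIndividuals(ref$sequences, cfg)
  expect_equal(nrow(truthGenotypes(ind$truth)), 0L)
  for (h in ind$haplotypes)
    expect_identical(as.character(h), as.character(ref$sequences))
})

test_that("a forced zygosity class makes every site an opposite
           homozygote", {
  cfg <- SimConfig(nGenes = 3L, snpRate = 5e-3,
                   zygosityMix = c(1, 0, 0, 0), seed = 5)
  ref <- simulateTranscriptome(cfg)
  g <- truthGenotypes(simulateIndividuals(ref$sequences, cfg)$truth)
  expect_gt(nrow(g), 0L)
  expect_true(all(g$category == "homT.homA"))
  expect_true(all((g$gtTame == "1/1" & g$gtAggr == "0/0") |
                    (g$gtTame == "0/0" & g$gtAggr == "1/1")))
})

test_that("planted site count follows the binomial expectation", {
  cfg <- SimConfig(nGenes = 1L, snpRate = 1e-3, seed = 17,
                   variantClassMix = c(1, 0, 0))
  ref <- simulateTranscriptome(cfg, forceLength = 10000)
  g <- truthGenotypes(simulateIndividuals(ref$sequences, cfg)$truth)
  expect_gte(nrow(g), 10 - 3 * sqrt(10))
  expect_lte(nrow(g), 10 + 3 * sqrt(10))
})

test_that("expression truth honours the DE design", {
  cfg0 <- SimConfig(nGenes = 30L, deFraction = 0, seed = 2)
  ab0 <- simulateExpression(cfg0)
  expect_identical(ab0$propTame, ab0$propAggr)
  expect_true(all(!ab0$isDE))

  cfg1 <- SimConfig(nGenes = 30L, deFraction = 0.3, deFold = 1,
                    seed = 2)
  expect_true(all(!simulateExpression(cfg1)$isDE))

  # one DE gene among many: its proportion ratio stays within the
  # renormalization correction (sum shifts by < 1% when the gene is
  # a small share of the library)
  cfg2 <- SimConfig(nGenes = 200L, deFraction = 1 / 200, deFold = 2,
                    abundanceLogSd = 1, seed = 8)
  ab2 <- simulateExpression(cfg2)
  de <- ab2[ab2$isDE, ]
  expect_equal(nrow(de), 1L)
  ratio <- if (de$direction == "T>A") de$propTame / de$propAggr else
    de$propAggr / de$propTame
  expect_lt(abs(ratio - 2) / 2, 0.02)
  expect_equal(sum(ab2$propTame), 1, tolerance = 1e-9)
  expect_equal(sum(ab2$propAggr), 1, tolerance = 1e-9)
})

test_that("error-free reads are exact haplotype substrings with correct
           truth placements", {
  cfg <- SimConfig(nGenes = 3L, nReadsPerSample = 20L,
                   subErrorRate = 0, homopolymerIndelCoeff = 0,
                   snpRate = 2e-3, seed = 9)
  sim <- simulateExperiment(cfg)
  origins <- truthReadOrigins(sim$truth)
  reads <- c(as.character(sim$reads$tame$reads),
             as.character(sim$reads$aggressive$reads))
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    hap <- as.character(sim$haplotypes[[o$haplotype]][[o$gene]])
    placements <- oracleExactPlacements(reads[[o$readId]], hap)
    hit <- vapply(placements, function(p)
      p$start == o$start & p$strand == o$strand, logical(1))
    expect_true(any(hit), label = paste("read", o$readId, "placement"))
  }
})

test_that("read counts, lengths and determinism match the model", {
  cfg <- SimConfig(nGenes = 5L, geneLengthMean = 3000,
                   geneLengthSd = 100, nReadsPerSample = 10000L,
                   snpRate = 0, seed = 21)
  ref <- simulateTranscriptome(cfg)
  ind <- simulateIndividuals(ref$sequences, cfg)
  ab <- simulateExpression(cfg)
  rd <- simulateReads(ind$haplotypes, ab, cfg)
  expect_length(rd$tame$reads, 10000L)
  expect_length(rd$aggressive$reads, 10000L)

  # mean observed length equals the truncated-normal mean within a CLT
  # band (truncation to [50, 600] pulls the raw mean of 376 down)
  mu <- 376; sd <- 148; lo <- 50; hi <- 600
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  truncMean <- mu + sd * (dnorm(a) - dnorm(b)) / z
  truncVar <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                        ((dnorm(a) - dnorm(b)) / z)^2)
  obs <- mean(Biostrings::width(rd$tame$reads))
  expect_lt(abs(obs - truncMean), 3 * sqrt(truncVar / 10000))

  rd2 <- simulateReads(ind$haplotypes, ab, cfg)
  expect_identical(as.character(rd$tame$reads),
                   as.character(rd2$tame$reads))
  expect_identical(as.character(rd$aggressive$qualities),
                   as.character(rd2$aggressive$qualities))
})

test_that("per-gene read counts follow the abundance profile", {
  cfg <- SimConfig(nGenes = 20L, nReadsPerSample = 20000L,
                   deFraction = 0, snpRate = 0, seed = 13)
  ref <- simulateTranscriptome(cfg)
  ind <- simulateIndividuals(ref$sequences, cfg)
  ab <- simulateExpression(cfg)
  rd <- simulateReads(ind$haplotypes, ab, cfg)
  counts <- table(factor(rd$tame$origins$gene, levels = ab$gene))
  gof <- suppressWarnings(
    stats::chisq.test(as.integer(counts), p = ab$propTame))
  expect_gt(gof$p.value, 0.001)
})

test_that("homopolymer indel errors appear at the configured scale", {
  cfg <- SimConfig(nGenes = 2L, geneLengthMean = 2000,
                   geneLengthSd = 10, nReadsPerSample = 2000L,
                   subErrorRate = 0, homopolymerIndelCoeff = 0.05,
                   snpRate = 0, seed = 31)
  ref <- simulateTranscriptome(cfg)
  ind <- simulateIndividuals(ref$sequences, cfg)
  ab <- simulateExpression(cfg)
  rd <- simulateReads(ind$haplotypes, ab, cfg)
  expect_gt(mean(rd$tame$origins$nIndel > 0), 0.5)
  cfg0 <- SimConfig(nGenes = 2L, nReadsPerSample = 200L,
                    subErrorRate = 0, homopolymerIndelCoeff = 0,
                    snpRate = 0, seed = 31)
  rd0 <- simulateReads(ind$haplotypes, ab, cfg0)
  expect_true(all(rd0$tame$origins$nIndel == 0))
})
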