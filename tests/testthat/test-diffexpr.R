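# Library totals of the two sequenced samples.
NT <- 2565892
NA_AGG <- 3379343

test_that("library normalization is plain division", {
  expect_equal(normalizeCounts(0, 100), 0)
  expect_equal(normalizeCounts(100, 100), 1)
  expect_equal(normalizeCounts(136, NT), 136 / NT)
  expect_equal(normalizeCounts(136, NT), 5.3004e-5, tolerance = 1e-4)
  expect_error(normalizeCounts(1, 0), "positive")
  expect_error(normalizeCounts(-1, 10), "non-negative")
})

test_that("fold changes reproduce the published validation genes", {
  scgn <- foldChange(136, NT, 402, NA_AGG)
  expect_equal(round(scgn$fold, 2), 2.24)
  expect_equal(scgn$direction, "A>T")
  itga8 <- foldChange(68, NT, 20, NA_AGG)
  expect_equal(round(itga8$fold, 2), 4.48)
  expect_equal(itga8$direction, "T>A")
})

test_that("fold change is symmetric and handles zeros by policy", {
  eq <- foldChange(50, 1000, 100, 2000)
  expect_equal(eq$fold, 1)
  expect_equal(eq$direction, "tie")

  a <- foldChange(30, 1000, 10, 1000)
  b <- foldChange(10, 1000, 30, 1000)
  expect_equal(a$fold, b$fold)
  expect_equal(a$direction, "T>A")
  expect_equal(b$direction, "A>T")

  z <- foldChange(8, 1000, 0, 1000)
  expect_true(is.na(z$fold))
  expect_equal(z$direction, "T>A")
  zp <- foldChange(8, 1000, 0, 1000, policy = "pseudocount_1")
  expect_equal(zp$fold, 9)
  zz <- foldChange(0, 1000, 0, 1000)
  expect_true(is.na(zz$fold))
  expect_equal(zz$direction, "tie")
})

test_that("the Z statistic behaves like a pooled two-proportion test", {
  expect_equal(zStatistic(25, 1000, 25, 1000), 0)
  expect_true(is.na(zStatistic(0, 1000, 0, 1000)))

  # closed form at xT = 0
  k <- 40; N <- 5e5
  pbar <- k / (2 * N)
  want <- (k / N) / sqrt(pbar * (1 - pbar) * (2 / N))
  expect_equal(zStatistic(0, N, k, N), want)

  # under the null the statistic is approximately standard normal
  set.seed(101)
  N <- 5e5; p <- 1e-4
  xT <- rbinom(1000, N, p); xA <- rbinom(1000, N, p)
  lam <- zStatistic(xT, N, xA, N)
  signed <- lam * sign(xT / N - xA / N)
  expect_lt(abs(mean(signed)), 0.1)
  expect_gt(stats::sd(signed), 0.9)
  expect_lt(stats::sd(signed), 1.1)
})

test_that("the two-sided p-value matches the normal tail identity", {
  expect_equal(pTwoSided(0), 1)
  expect_equal(pTwoSided(1.959964), 0.05, tolerance = 1e-4)
  expect_equal(pTwoSided(-2), pTwoSided(2))
  lams <- seq(0, 5, by = 0.25)
  expect_true(all(diff(pTwoSided(lams)) < 0))
})

test_that("the screen applies both the fold and the p cutoffs", {
  mk <- function(fold, p, dir) data.frame(
    gene = "g", fold = fold, p = p, direction = dir)
  expect_false(deScreen(mk(1.9, 0.001, "T>A"))$table$passesScreen)
  expect_false(deScreen(mk(3.0, 0.2, "T>A"))$table$passesScreen)
  expect_true(deScreen(mk(2.0, 0.01, "T>A"))$table$passesScreen)

  # ten-gene fixture with four known passers: 3 up-tame, 1 up-aggr
  fix <- data.frame(
    gene = paste0("g", 1:10),
    fold = c(3, 2.5, 2.1, 4, 1.2, 1.9, 5, 2.2, NA, 3),
    p = c(0.001, 0.02, 0.04, 0.01, 0.001, 0.001, 0.2, 0.6, 0.01,
          0.03),
    direction = c("T>A", "T>A", "T>A", "A>T", "T>A", "T>A", "T>A",
                  "A>T", "T>A", "tie"))
  sc <- deScreen(fix)
  expect_equal(unname(sc$tally["upTame"]), 3L)
  expect_equal(unname(sc$tally["upAggr"]), 1L)
})

test_that("deTable assembles results ordered by significance", {
  counts <- data.frame(gene = c("a", "b", "c"),
                       countT = c(136L, 68L, 10L),
                       countA = c(402L, 20L, 12L))
  tab <- deTable(counts, NT, NA_AGG)
  expect_equal(nrow(tab), 3L)
  expect_true(!is.unsorted(tab$p))
  expect_equal(round(tab$fold[tab$gene == "a"], 2), 2.24)
  expect_true(all(tab$direction[tab$gene == "a"] == "A>T"))
})

test_that("MA normalization identity holds on a uniformly scaled
           fixture", {
  set.seed(121)
  base <- rpois(100, 200) + 1L
  ratio <- 3L                       # library-size ratio N_A / N_T
  counts <- data.frame(gene = sprintf("g%03d", 1:100),
                       countT = base,
                       countA = as.integer(base * ratio))
  NTloc <- sum(counts$countT); NAloc <- sum(counts$countA)
  ma <- maData(counts, NTloc, NAloc)
  expect_equal(unname(ma$medianM["pre"]), -log2(NAloc / NTloc),
               tolerance = 1e-9)
  expect_lt(abs(ma$medianM["post"]), 1e-6)

  # a gene with equal counts and totals sits at M = 0
  one <- maData(data.frame(gene = "g", countT = 50L, countA = 50L),
                1000, 1000)
  expect_equal(one$post$M, 0)
})

test_that("relative qPCR expression follows 2^-ddCt", {
  expect_equal(ddCtRelativeExpression(20, 20, 20, 20), 1)
  expect_equal(ddCtRelativeExpression(21, 20, 20, 20), 0.5)
  expect_equal(ddCtRelativeExpression(18, 20, 19.8, 18.6), 9.190,
               tolerance = 1e-3)
})
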