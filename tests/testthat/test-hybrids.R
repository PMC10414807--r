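test_that("hybrid genotypes follow the homozygous-parent rules", {
  d <- matrix(c(
    2L, 0L,
    2L, 2L,
    0L, 0L,
    1L, 0L,
    NA, 2L
  ), nrow = 5, byrow = TRUE, dimnames = list(NULL, c("p1", "p2")))
  p <- make_panel(d, gerp = rep(1, 5))
  ped <- data.frame(hybrid_id = "h1", parent1 = "p1", parent2 = "p2")
  h <- inferHybrids(p, ped)
  expect_identical(unname(dosage(h)[, 1]), c(1L, 2L, 0L, NA, NA))
  expect_true(sampleData(h)$is_hybrid)

  expect_error(
    inferHybrids(p, data.frame(hybrid_id = "h", parent1 = "p1", parent2 = "zz")),
    "unknown parent"
  )

  # seeded gamete sampling resolves heterozygous parents deterministically
  h1 <- inferHybrids(p, ped, gamete_sampling = TRUE, seed = 5)
  h2 <- inferHybrids(p, ped, gamete_sampling = TRUE, seed = 5)
  expect_identical(dosage(h1), dosage(h2))
  expect_true(dosage(h1)[4, 1] %in% c(0L, 1L))
})

test_that("heterozygosity fractions count carrier sites per class and DAF bin", {
  d <- matrix(c(1L, 1L, 2L, 0L, NA, 1L), ncol = 1,
    dimnames = list(NULL, "h1")
  )
  p <- make_panel(d, gerp = rep(1, 6), polarized = TRUE)
  hf <- hetFraction(p)
  expect_equal(hf$fraction[hf$daf_bin == "all"], 3 / 4)

  # denominator option: all called class sites
  hf2 <- hetFraction(p, denominator = "segregating")
  expect_equal(hf2$fraction[hf2$daf_bin == "all"], 3 / 5)

  # DAF deciles are (0, 0.1], ..., (0.9, 1]
  daf <- c(0.05, 0.1, 0.15, 0.95, 0.4, NA)
  hf3 <- hetFraction(p, daf = daf)
  b1 <- hf3[hf3$daf_bin == "1", ]
  expect_equal(b1$denominator, 2L) # sites 1 and 2 (0.1 falls in bin 1)
  expect_equal(b1$fraction, 1)
  b10 <- hf3[hf3$daf_bin == "10", ]
  expect_equal(b10$denominator, 0L)
  expect_true(is.na(b10$fraction))
})

test_that("inferred-hybrid het fractions equal gamete-union accounting", {
  set.seed(21)
  np <- 12
  d <- matrix(sample(c(0L, 2L), 60 * np, replace = TRUE), nrow = 60)
  colnames(d) <- sprintf("p%02d", 1:np)
  p <- make_panel(d, gerp = runif(60, -2, 6))
  ped <- hypotheticalHybrids(colnames(d), n = 10, seed = 2)
  names(ped)[1] <- "hybrid_id"
  h <- inferHybrids(p, ped)
  hf <- hetFraction(h)
  # oracle: homozygous parents pass exactly one allele each
  for (i in seq_len(nrow(ped))) {
    g <- (d[, ped$parent1[i]] + d[, ped$parent2[i]]) / 2
    for (cl in unique(hf$class)) {
      rows <- severity(p) == cl
      expected <- sum(g[rows] == 1) / sum(g[rows] >= 1)
      got <- hf$fraction[hf$hybrid_id == ped$hybrid_id[i] & hf$class == cl &
        hf$daf_bin == "all"]
      expect_equal(got, expected)
    }
  }
})

test_that("paired heterozygosity test handles degenerate inputs", {
  expect_error(pairedHetTest(c(.1, .2), c(.1, .2)), "at least 3")

  same <- pairedHetTest(c(.1, .2, .3), c(.1, .2, .3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  const <- pairedHetTest(c(.2, .3, .4), c(.1, .2, .3))
  expect_true(const$degenerate)
  expect_equal(const$t, Inf)
  expect_equal(const$p_value, 0)

  sym <- pairedHetTest(c(.2, .0, .2, .0), c(.1, .1, .1, .1))
  expect_equal(sym$t, 0, tolerance = 1e-12)

  x <- c(.30, .28, .35, .31, .29)
  y <- c(.20, .22, .25, .21, .19)
  got <- pairedHetTest(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
})

test_that("window correlation relates deleterious and heterozygous density", {
  # 5 windows x 40 SNPs each; deleterious share rises across windows and the
  # hybrid heterozygosity is made to track it exactly
  pos <- as.vector(sapply(0:4, function(w) w * 1e6 + seq(1000, by = 20000, length.out = 40)))
  n_del <- c(4, 8, 16, 24, 32)
  gerp <- unlist(lapply(n_del, function(k) c(rep(1, k), rep(-1, 40 - k))))
  d <- matrix(0L, 200, 10)
  het_rate <- rep(n_del / 40, each = 40)
  set.seed(5)
  for (j in 1:10) d[, j] <- rbinom(200, 1L, het_rate)
  p <- make_panel(d, pos = pos, gerp = gerp)
  wc <- windowDensityCorrelation(p, class = "SLIGHT", min_snps = 20)
  expect_equal(nrow(wc$windows), 5)
  expect_equal(wc$windows$x, n_del / 40)
  expect_gt(wc$pearson_r, 0.9)

  # constant heterozygosity -> undefined correlation
  d2 <- matrix(1L, 200, 4)
  p2 <- make_panel(d2, pos = pos, gerp = gerp)
  wc2 <- windowDensityCorrelation(p2, class = "SLIGHT")
  expect_true(is.na(wc2$pearson_r))

  expect_error(
    windowDensityCorrelation(p[1:40, ], class = "SLIGHT"),
    "fewer than 3"
  )
})

test_that("hypothetical hybrids draw distinct pairs deterministically", {
  expect_equal(
    hypotheticalHybrids(c("a", "b"), n = 1, seed = 3)[, c("parent1", "parent2")],
    data.frame(parent1 = "a", parent2 = "b")
  )
  ids <- sprintf("p%02d", 1:20)
  h1 <- hypotheticalHybrids(ids, n = 50, seed = 7)
  h2 <- hypotheticalHybrids(ids, n = 50, seed = 7)
  expect_identical(h1, h2)
  key <- paste(h1$parent1, h1$parent2)
  expect_equal(anyDuplicated(key), 0L)
  expect_error(hypotheticalHybrids(c("a", "b"), n = 2), "only 1 distinct")
})

test_that("load-by-year trend returns Pearson correlation with guards", {
  up <- loadYearTrend(c(10, 12, 15, 18), c(1990, 1995, 2000, 2005))
  expect_equal(up$pearson_r, cor(c(10, 12, 15, 18), c(1990, 1995, 2000, 2005)))
  expect_error(loadYearTrend(c(1, 2), c(1990, 2000)), "at least 3")
  flat <- loadYearTrend(c(5, 5, 5), c(1990, 2000, 2010))
  expect_true(is.na(flat$pearson_r))
})
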