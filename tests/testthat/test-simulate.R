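test_that("the generator is deterministic under a seed", {
  s1 <- simulateILs(small_sim_config(seed = 11))
  s2 <- simulateILs(small_sim_config(seed = 11))
  expect_identical(dosage(s1$panel), dosage(s2$panel))
  expect_identical(siteData(s1$panel), siteData(s2$panel))
  s3 <- simulateILs(small_sim_config(seed = 12))
  expect_false(identical(dosage(s1$panel), dosage(s3$panel)))

  p1 <- makeCrosses(s1$panel, 20, seed = 4)
  p2 <- makeCrosses(s1$panel, 20, seed = 4)
  expect_identical(p1, p2)
})

test_that("configuration invariants are enforced", {
  expect_error(
    simConfig(era_schedule = data.frame(
      label = "A", Ne = 50L, generations = 5L, selfing = 1.2,
      sample_n = 10L, year = 2000, country = "CN"
    )),
    "selfing"
  )
  expect_error(
    simConfig(era_schedule = data.frame(
      label = "A", Ne = 2L, generations = 5L, selfing = 0.5,
      sample_n = 100L, year = 2000, country = "CN"
    )),
    "sample_n"
  )
  expect_error(
    simConfig(severity_mix = c(NONDEL = 0.5, SLIGHT = 0.2, MODERATE = 0.2, STRONG = 0.2))
  )
})

test_that("panel metadata matches the era schedule", {
  sim <- simulateILs(small_sim_config(seed = 13))
  md <- sampleData(sim$panel)
  expect_equal(unname(table(md$era)[c("E1", "E2", "E3")]), rep(20L, 3),
    ignore_attr = TRUE
  )
  expect_setequal(unique(md$heterotic_group), c("SS", "NSS", "IDT", "HZS"))
  expect_false(any(md$is_hybrid))
  expect_false(polarized(sim$panel))
  # outgroup mismatches exercise the exclusion path
  pp <- polarizePanel(sim$panel)
  expect_gt(attr(pp, "n_excluded"), 0)
})

test_that("crosses respect group membership constraints", {
  sim <- simulateILs(small_sim_config(seed = 14))
  md <- sampleData(sim$panel)
  ped_b <- makeCrosses(sim$panel, 40, within_group = FALSE, seed = 1)
  g1 <- md[ped_b$parent1, "heterotic_group"]
  g2 <- md[ped_b$parent2, "heterotic_group"]
  expect_true(all(g1 != g2))

  ped_w <- makeCrosses(sim$panel, 40, within_group = TRUE, seed = 1)
  w1 <- md[ped_w$parent1, "heterotic_group"]
  w2 <- md[ped_w$parent2, "heterotic_group"]
  expect_true(all(w1 == w2))

  expect_equal(nrow(makeCrosses(sim$panel, 0)), 0)
  expect_error(makeCrosses(sim$panel, 1e6), "insufficient")
  expect_true(all(ped_b$year >= md[ped_b$parent1, "year"]))
})

test_that("neutral classes drift together and selected classes are purged", {
  # neutrality: no selection anywhere, common initial spectrum -> the mean
  # DAF change of SLIGHT sites is indistinguishable from NONDEL sites
  cfg0 <- small_sim_config(seed = 15, n_sites = 400L)
  cfg0$s_map[] <- 0
  cfg0$init_freq_deleterious <- cfg0$init_freq
  cfg0$deleterious_private_frac <- 0
  sim0 <- simulateILs(cfg0)
  shift <- sim0$truth$era_freq[3, ] - sim0$truth$q0
  pv <- wilcox.test(
    shift[sim0$truth$class == "SLIGHT"],
    shift[sim0$truth$class == "NONDEL"]
  )$p.value
  expect_gt(pv, 0.001)

  # strong purifying selection drives derived frequencies down
  cfgS <- small_sim_config(seed = 16, n_sites = 400L)
  cfgS$deleterious_private_frac <- 0
  cfgS$init_freq_deleterious <- c(0.2, 0.4)
  simS <- simulateILs(cfgS)
  strong <- simS$truth$class == "STRONG"
  expect_lt(
    mean(simS$truth$era_freq[3, strong]),
    mean(simS$truth$q0[strong])
  )
})

test_that("neutral mean frequency is a martingale within Monte-Carlo error", {
  cfg <- small_sim_config(seed = 17, n_sites = 500L)
  cfg$s_map[] <- 0
  cfg$init_freq <- c(0.2, 0.4)
  cfg$init_freq_deleterious <- c(0.2, 0.4)
  cfg$deleterious_private_frac <- 0
  sim <- simulateILs(cfg)
  final <- sim$truth$era_freq[3, ]
  drift <- final - sim$truth$q0
  expect_lt(abs(mean(drift)), 3 * sd(drift) / sqrt(length(drift)))
})

test_that("simulated phenotypes hit their architecture targets", {
  X <- simulateGenotypes(150, 400, seed = 51)
  expect_error(simulatePhenotypes(X, h2_A = 0.7, h2_D = 0.3), "< 1")

  ph <- simulatePhenotypes(X, h2_A = 0.5, h2_D = 0.1, seed = 52)
  expect_equal(ph$h2_A, 0.5, tolerance = 0.15)
  ph2 <- simulatePhenotypes(X, h2_A = 0.5, h2_D = 0.1, seed = 52)
  expect_identical(ph$y, ph2$y)

  # no additive signal: phenotype uncorrelated with the true genetic score
  ph0 <- simulatePhenotypes(X, h2_A = 0, h2_D = 0, seed = 53)
  gscore <- drop(X %*% rnorm(400))
  expect_lt(abs(cor(ph0$y, gscore)), 0.25)

  # inflation scales deleterious effect sizes
  classes <- factor(rep(c("NONDEL", "SLIGHT"), each = 200),
    levels = c("NONDEL", "SLIGHT", "MODERATE", "STRONG")
  )
  phi <- simulatePhenotypes(X,
    classes = classes, h2_A = 0.5, h2_D = 0,
    deleterious_inflation = 3, seed = 54
  )
  a <- phi$effects$a
  expect_gt(
    mean(abs(a[201:400][a[201:400] != 0])),
    mean(abs(a[1:200][a[1:200] != 0]))
  )
})

test_that("DEG labelling thins deleterious sites out of DEG regions", {
  sim <- simulateILs(small_sim_config(seed = 18, n_sites = 400L))
  pp <- annotateSeverity(polarizePanel(sim$panel, drop_excluded = FALSE))
  expect_error(
    simulateDegLabels(pp, sim$genes, promoter_depletion = 1.5),
    "\\[0, 1\\]"
  )
  res <- simulateDegLabels(pp, sim$genes,
    frac_deg = 0.4,
    promoter_depletion = 0.8, seed = 19
  )
  expect_setequal(res$labels$gene_id, sim$genes$gene_id)
  # relocation empties DEG regions of most deleterious sites
  sizes <- setNames(5e6, "chr1")
  rg <- buildGeneRegions(sim$genes, sizes)
  deg_region <- GenomicRanges::reduce(rg$combined[res$labels$is_deg])
  in_deg <- function(panel) {
    rr <- SummarizedExperiment::rowRanges(panel)[severity(panel) != "NONDEL"]
    sum(GenomicRanges::countOverlaps(rr, deg_region) > 0)
  }
  expect_lt(in_deg(res$panel), in_deg(pp))
  # nondeleterious placement untouched
  nd <- function(panel) {
    rr <- SummarizedExperiment::rowRanges(panel)[severity(panel) == "NONDEL"]
    sum(GenomicRanges::countOverlaps(rr, deg_region) > 0)
  }
  expect_equal(nd(res$panel), nd(pp))
  # site order remains sorted after relocation
  ps <- GenomicRanges::start(SummarizedExperiment::rowRanges(res$panel))
  expect_true(all(diff(ps) > 0))
})

test_that("a simulated panel round-trips through the VCF surface", {
  sim <- simulateILs(small_sim_config(seed = 20, n_sites = 150L))
  f <- tempfile(fileext = ".vcf")
  writeVcfPanel(sim$panel, f)
  back <- readVcfPanel(f)
  expect_identical(unname(dosage(back)), unname(dosage(sim$panel)))
  expect_equal(siteData(back)$gerp, siteData(sim$panel)$gerp, tolerance = 1e-10)
  expect_identical(siteData(back)$ancestral, siteData(sim$panel)$ancestral)
})
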