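chrom_sizes <- c(chr1 = 1e6)

test_that("promoters are 2 kb upstream, strand aware, clipped at the boundary", {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(5001, 5001, 501), end = c(8000, 8000, 900)),
    strand = c("+", "-", "+"),
    gene_id = c("gp", "gm", "gc")
  )
  rg <- buildGeneRegions(genes, chrom_sizes)
  # + strand: [start - 2000, start)
  expect_equal(GenomicRanges::start(rg$promoter)[1], 3001)
  expect_equal(GenomicRanges::end(rg$promoter)[1], 5000)
  # - strand: (end, end + 2000]
  expect_equal(GenomicRanges::start(rg$promoter)[2], 8001)
  expect_equal(GenomicRanges::end(rg$promoter)[2], 10000)
  # clipped at position 1: length 500
  expect_equal(GenomicRanges::start(rg$promoter)[3], 1)
  expect_equal(GenomicRanges::width(rg$promoter)[3], 500)
  # combined = contiguous promoter + body
  expect_equal(GenomicRanges::start(rg$combined)[1], 3001)
  expect_equal(GenomicRanges::end(rg$combined)[1], 8000)

  out <- GenomicRanges::GRanges("chr1", IRanges::IRanges(999000, 1000500),
    strand = "+", gene_id = "gx"
  )
  expect_error(buildGeneRegions(out, chrom_sizes), "bounds")
})

test_that("region counting is closed-interval exact at boundaries", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, end = 8000),
    strand = "+", gene_id = "g1"
  )
  rg <- buildGeneRegions(genes, chrom_sizes)
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(3001, 3000, 5000, 5001, 8000, 8001),
    width = 1
  ))
  cnt <- countInRegions(sites, rg)
  expect_equal(cnt$promoter, 2) # 3001 (5' edge) and 5000; 3000 is outside
  expect_equal(cnt$body, 2) # 5001 and 8000; 8001 is past the end
  expect_equal(cnt$combined, 4)

  empty <- countInRegions(sites[0], rg)
  expect_equal(empty$combined, 0)
})

test_that("interval counts match all-pairs brute force", {
  set.seed(31)
  for (rep in 1:5) {
    n_genes <- 40
    starts <- sort(sample(10000:900000, n_genes))
    genes <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(starts, width = sample(500:3000, n_genes, TRUE)),
      strand = sample(c("+", "-"), n_genes, TRUE),
      gene_id = sprintf("g%03d", 1:n_genes)
    )
    rg <- buildGeneRegions(genes, chrom_sizes)
    pos <- sample(1:1e6, 800)
    sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))
    cnt <- countInRegions(sites, rg)
    for (region in c("promoter", "body", "combined")) {
      expect_equal(
        cnt[[region]],
        brute_region_counts(
          pos,
          GenomicRanges::start(rg[[region]]), GenomicRanges::end(rg[[region]])
        )
      )
    }
  }
})

test_that("DEG contrast detects depletion and errors without both labels", {
  set.seed(32)
  n <- 60
  counts <- data.frame(
    gene_id = rep(sprintf("g%02d", 1:n), 2),
    class = rep(c("SLIGHT", "NONDEL"), each = n),
    promoter = c(rpois(n / 2, 1), rpois(n / 2, 6), rpois(n, 4)),
    body = c(rpois(n / 2, 1), rpois(n / 2, 6), rpois(n, 4))
  )
  counts$combined <- counts$promoter + counts$body
  labels <- data.frame(
    gene_id = sprintf("g%02d", 1:n),
    is_deg = rep(c(TRUE, FALSE), each = n / 2)
  )
  res <- degContrast(counts, labels, deleterious_classes = "SLIGHT")
  expect_lt(res$promoter$wilcox_p, 0.001)
  expect_lt(res$promoter$median_deg, res$promoter$median_nondeg)
  # control classes have no DEG structure here
  expect_gt(res$control$promoter$wilcox_p, 0.001)

  labels_one <- labels
  labels_one$is_deg <- TRUE
  expect_error(degContrast(counts, labels_one), "both DEG and non-DEG")
})

test_that("QTL enrichment matches hand-computed statistics", {
  qtl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500000))
  at <- function(pos) GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))

  # equal in-QTL proportions: Z = 0
  del <- at(c(100, 600000))
  ndl <- at(c(200, 700000, 300, 800000))
  r0 <- qtlEnrichment(del, ndl, qtl)
  expect_equal(r0$z, 0)

  # 2x2 proportional rows: chi-square 0
  syn <- at(c(1000, 2000, 650000, 750000))
  r1 <- qtlEnrichment(del, ndl, qtl, syn_sites = syn)
  expect_equal(unname(r1$chisq), 0)

  # [[30,70],[10,90]]: expected 20/80 each row, chi2 = 5 + 1.25 + 5 + 1.25
  del2 <- at(c(sample(1:500000, 30), sample(500001:999999, 70)))
  syn2 <- at(c(sample(1:500000, 10), sample(500001:999999, 90)))
  r2 <- qtlEnrichment(del2, ndl, qtl, syn_sites = syn2)
  expect_equal(unname(r2$chisq), 12.5)

  # manual one-proportion Z for the same table against p0 = 1/2
  ndl_half <- at(c(1000, 600000))
  r3 <- qtlEnrichment(del2, ndl_half, qtl, del_classes = rep("SLIGHT", 100))
  expect_equal(r3$z, (0.3 - 0.5) / sqrt(0.5 * 0.5 / 100))
  expect_equal(r3$per_class$z[1], r3$z)

  # degenerate null proportion
  r4 <- qtlEnrichment(del2, at(c(1000, 2000)), qtl)
  expect_true(is.na(r4$z))
  expect_error(qtlEnrichment(del[0], ndl, qtl), "non-empty")
})

test_that("candidate-locus contrast uses exact rank statistics", {
  dos <- c(rep(2L, 5), rep(0L, 5), 1L)
  trait <- c(1:5, 11:15, 8) # disjoint: every derived value below every ancestral
  res <- candidateContrast(dos, trait)
  # exact two-sided rank-sum p for complete separation of 5 vs 5:
  # 2 / C(10,5) = 2/252
  expect_equal(res$trait_p, 2 / 252)
  expect_equal(res$n_derived, 5)
  expect_equal(res$trait_median_derived, 3)

  expr <- c(5:1, 15:11, 9)
  res2 <- candidateContrast(dos, trait, expr)
  expect_equal(res2$expression_p, 2 / 252)

  expect_error(candidateContrast(rep(1L, 10), trait[1:10]), "homozygote")
})
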