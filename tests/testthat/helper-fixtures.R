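# small in-code fixtures and independent brute-force oracles

# GenoPanel from a dosage matrix (sites x samples)
make_panel <- function(dosage, pos = NULL, chrom = "chr1", gerp = NULL,
                       ancestral = NULL, colData = NULL, polarized = TRUE,
                       chrom_len = NULL) {
  n_sites <- nrow(dosage)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = n_sites)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
  }
  ref <- rep("A", n_sites)
  alt <- rep("T", n_sites)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pos, width = 1L),
    ref = ref, alt = alt,
    ancestral = if (is.null(ancestral)) ref else ancestral,
    gerp = if (is.null(gerp)) rep(1, n_sites) else gerp
  )
  if (!is.null(chrom_len)) {
    GenomeInfoDb::seqlengths(gr) <- setNames(chrom_len, chrom)
  }
  p <- GenoPanel(dosage, gr, colData = colData, polarized = polarized)
  annotateSeverity(p)
}

# direct per-sample load counting by explicit iteration
brute_load <- function(d, mode) {
  out <- numeric(ncol(d))
  for (s in seq_len(ncol(d))) {
    cnt <- 0L
    for (i in seq_len(nrow(d))) {
      g <- d[i, s]
      if (is.na(g)) next
      cnt <- cnt + if (mode == "additive") g else as.integer(g == 2L)
    }
    out[s] <- cnt
  }
  out
}

# explicit-window ROH caller mirroring the published scan definition
brute_roh <- function(g, pos, window_snps, max_missing, max_het,
                      min_length, hit_fraction = 0.05) {
  L <- length(g)
  if (L < window_snps) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  n_win <- L - window_snps + 1L
  pass <- logical(n_win)
  for (w in seq_len(n_win)) {
    win <- g[w:(w + window_snps - 1L)]
    pass[w] <- sum(win == 1L, na.rm = TRUE) <= max_het &&
      sum(is.na(win)) <= max_missing
  }
  in_roh <- logical(L)
  for (i in seq_len(L)) {
    cover <- max(1L, i - window_snps + 1L):min(n_win, i)
    in_roh[i] <- mean(pass[cover]) >= hit_fraction
  }
  segs <- list()
  i <- 1L
  while (i <= L) {
    if (in_roh[i]) {
      j <- i
      while (j < L && in_roh[j + 1L]) j <- j + 1L
      if (pos[j] - pos[i] + 1 >= min_length) {
        segs[[length(segs) + 1L]] <- c(pos[i], pos[j])
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(segs)) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  m <- do.call(rbind, segs)
  data.frame(start = m[, 1], end = m[, 2])
}

# all-pairs membership counting for gene regions (1-based closed intervals)
brute_region_counts <- function(site_pos, region_start, region_end) {
  vapply(seq_along(region_start), function(i) {
    sum(site_pos >= region_start[i] & site_pos <= region_end[i])
  }, numeric(1))
}

# small era-structured simulation used by several test files
small_sim_config <- function(seed = 1, n_sites = 300L) {
  simConfig(
    n_sites = n_sites, chrom_length = 5e6,
    era_schedule = data.frame(
      label = c("E1", "E2", "E3"),
      Ne = c(80L, 50L, 30L), generations = c(8L, 8L, 8L),
      selfing = c(0.5, 0.7, 0.95), sample_n = c(20L, 20L, 20L),
      year = c(1965, 1990, 2010), country = "CN"
    ),
    seed = seed
  )
}
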