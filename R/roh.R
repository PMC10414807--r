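#' Thin SNPs to one per window
#'
#' Keeps the first SNP in every non-overlapping `spacing`-bp bin per
#' chromosome, so that runs of homozygosity reflect autozygosity rather than
#' local marker clustering.
#'
#' @param sites `GRanges` of SNP positions (width 1), sorted within
#'   chromosomes.
#' @param spacing bin width in bp.
#' @return integer vector of retained site indices.
#' @export
thinSNPs <- function(sites, spacing = 2000L) {
  if (!length(sites)) {
    return(integer(0))
  }
  chrom <- as.character(GenomeInfoDb::seqnames(sites))
  pos <- GenomicRanges::start(sites)
  bin <- paste0(chrom, ":", (pos - 1L) %/% spacing)
  which(!duplicated(bin))
}

#' Method-of-moments inbreeding coefficient
#'
#' Per-sample `F = (O_hom - E_hom) / (L - E_hom)` where `O_hom` is the
#' observed number of homozygous calls, `L` the number of called polymorphic
#' sites, and `E_hom` the expected homozygosity under Hardy-Weinberg with the
#' small-sample correction `1 - 2 p (1-p) * 2n / (2n - 1)` summed over the
#' sample's called sites (the VCFtools `--het` convention). Monomorphic sites
#' are excluded.
#'
#' @param panel a [GenoPanel-class] (>= 2 samples).
#' @return data.frame with `sample_id`, `O_hom`, `E_hom`, `n_sites`, `F`
#'   (`NA` when no polymorphic site is called).
#' @export
inbreedingF <- function(panel) {
  d <- dosage(panel)
  if (ncol(d) < 2) stop("need >= 2 samples to estimate allele frequencies")
  called_n <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * called_n)
  poly <- !is.na(p) & p > 0 & p < 1 & called_n >= 2
  d <- d[poly, , drop = FALSE]
  p <- p[poly]
  n <- called_n[poly]
  e_site <- 1 - 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  called <- !is.na(d)
  O_hom <- colSums(d != 1L, na.rm = TRUE)
  E_hom <- as.numeric(crossprod(called, e_site))
  L <- colSums(called)
  ids <- colnames(d)
  if (is.null(ids)) ids <- paste0("sample", seq_len(ncol(d)))
  data.frame(
    sample_id = ids, O_hom = as.integer(O_hom), E_hom = E_hom,
    n_sites = as.integer(L),
    F = ifelse(L - E_hom > 0, (O_hom - E_hom) / (L - E_hom), NA_real_),
    row.names = NULL
  )
}

#' Runs of homozygosity by sliding-window scan
#'
#' PLINK-style scan on (thinned) SNPs: windows of `window_snps` consecutive
#' SNPs slide by one; a window passes if it contains at most `max_het`
#' heterozygous and `max_missing` missing calls. A SNP is in ROH when the
#' fraction of passing windows covering it reaches `hit_fraction`; maximal
#' runs of in-ROH SNPs become segments spanning the first to the last SNP,
#' kept when at least `min_length` bp long.
#'
#' @param panel a [GenoPanel-class] (thin first with [thinSNPs()] if desired).
#' @param window_snps SNPs per scanning window.
#' @param max_missing,max_het window tolerance for missing and heterozygous
#'   calls.
#' @param min_length minimum segment length in bp.
#' @param hit_fraction minimum fraction of passing windows covering a SNP.
#' @param samples optional subset of samples.
#' @return data.frame with `sample_id`, `chrom`, `start`, `end`, `length`,
#'   `n_snps`, `n_het`, `n_missing` (zero rows when nothing is called).
#' @export
detectROH <- function(panel, window_snps = 20L, max_missing = 2L, max_het = 1L,
                      min_length = 3e5, hit_fraction = 0.05, samples = NULL) {
  d <- dosage(panel)
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  rr <- SummarizedExperiment::rowRanges(panel)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ids <- colnames(d)
  if (is.null(ids)) ids <- paste0("sample", seq_len(ncol(d)))
  res <- list()
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    rows <- rows[order(pos[rows])]
    L <- length(rows)
    if (L < window_snps) next
    pp <- pos[rows]
    for (s in seq_along(ids)) {
      g <- d[rows, s]
      in_roh <- .roh_scan(g, window_snps, max_missing, max_het, hit_fraction)
      segs <- .runs_of(in_roh)
      for (r in seq_len(nrow(segs))) {
        i1 <- segs[r, 1]
        i2 <- segs[r, 2]
        len <- pp[i2] - pp[i1] + 1
        if (len < min_length) next
        gg <- g[i1:i2]
        res[[length(res) + 1L]] <- data.frame(
          sample_id = ids[s], chrom = ch, start = pp[i1], end = pp[i2],
          length = len, n_snps = i2 - i1 + 1L,
          n_het = sum(gg == 1L, na.rm = TRUE), n_missing = sum(is.na(gg)),
          row.names = NULL
        )
      }
    }
  }
  if (!length(res)) {
    return(data.frame(
      sample_id = character(), chrom = character(), start = numeric(),
      end = numeric(), length = numeric(), n_snps = integer(),
      n_het = integer(), n_missing = integer()
    ))
  }
  do.call(rbind, res)
}

# which SNPs are in ROH for one genotype vector
.roh_scan <- function(g, window_snps, max_missing, max_het, hit_fraction) {
  L <- length(g)
  n_win <- L - window_snps + 1L
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- cumsum(c(0L, het))
  cm <- cumsum(c(0L, mis))
  w <- seq_len(n_win)
  pass <- (ch[w + window_snps] - ch[w]) <= max_het &
    (cm[w + window_snps] - cm[w]) <= max_missing
  # windows covering SNP i: max(1, i - w + 1) .. min(n_win, i)
  cp <- cumsum(c(0L, as.integer(pass)))
  i <- seq_len(L)
  lo <- pmax(1L, i - window_snps + 1L)
  hi <- pmin(n_win, i)
  n_pass <- cp[hi + 1L] - cp[lo]
  n_cov <- hi - lo + 1L
  n_pass / n_cov >= hit_fraction
}

# maximal runs of TRUE; matrix of (start, end) indices
.runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts, ends)[r$values, , drop = FALSE]
}
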