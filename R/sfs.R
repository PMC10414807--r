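#' Projected derived site frequency spectrum
#'
#' Computes the expected derived SFS for a group of samples projected down to
#' `n_project` haploid genomes. Rather than taking one random subsample, each
#' site contributes its full hypergeometric projection: a site with `k` derived
#' copies among `m` called haplotypes adds `P(j | k, m, n_project)` to bin `j`.
#' This is the deterministic expectation of the downsampling used by SFS tools
#' and preserves total site mass. Sites with fewer than `n_project` called
#' haplotypes are dropped (counted in `n_dropped`).
#'
#' @param panel polarized [GenoPanel-class].
#' @param samples sample names/indices of the group.
#' @param n_project haploid projection size (>= 2), e.g. `2 * 30` for a group
#'   downsampled to 30 diploids.
#' @param class optional severity class restricting the sites.
#' @param bins number of equal frequency bins for the re-aggregated spectrum.
#' @return list with `n_project`, `expected_counts` (length `n_project + 1`,
#'   derived copies 0..n), `bins20` (counts re-aggregated over frequency bins
#'   in (0, 1]), `n_sites`, `n_dropped`, `class`.
#' @export
projectSFS <- function(panel, samples = NULL, n_project, class = NULL,
                       bins = 20L) {
  if (n_project < 2) stop("n_project must be >= 2")
  if (!polarized(panel)) stop("panel must be polarized")
  d <- dosage(panel)
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  if (!is.null(class)) {
    sv <- severity(panel)
    d <- d[!is.na(sv) & sv == class, , drop = FALSE]
  }
  k <- rowSums(d, na.rm = TRUE)
  m <- 2L * rowSums(!is.na(d))
  ok <- m >= n_project
  spec <- .project_counts(k[ok], m[ok], n_project)
  list(
    n_project = n_project, expected_counts = spec,
    bins20 = .bin_spectrum(spec, bins),
    n_sites = sum(ok), n_dropped = sum(!ok), class = class
  )
}

# expected projected spectrum for derived counts k out of m haplotypes
.project_counts <- function(k, m, n) {
  spec <- numeric(n + 1)
  if (!length(k)) {
    return(spec)
  }
  combos <- unique(cbind(k, m))
  tab <- table(paste(k, m))
  for (i in seq_len(nrow(combos))) {
    ki <- combos[i, 1]
    mi <- combos[i, 2]
    w <- tab[[paste(ki, mi)]]
    spec <- spec + w * dhyper(0:n, ki, mi - ki, n)
  }
  spec
}

# aggregate bins 1..n (frequencies j/n in (0,1]) into `bins` equal bins
.bin_spectrum <- function(spec, bins = 20L) {
  n <- length(spec) - 1L
  j <- seq_len(n)
  idx <- pmin(bins, ceiling(bins * j / n))
  out <- numeric(bins)
  for (b in seq_len(bins)) out[b] <- sum(spec[1L + j[idx == b]])
  names(out) <- sprintf("(%.2f,%.2f]", (seq_len(bins) - 1) / bins, seq_len(bins) / bins)
  out
}

#' Joint site frequency spectrum between two groups
#'
#' Projects both groups to the common haploid size `2 * min(|A|, |B|)` and
#' accumulates, per shared site, the outer product of the two hypergeometric
#' projection distributions. Marginals of the result equal the one-dimensional
#' projected spectra on the same sites.
#'
#' @param panel polarized [GenoPanel-class].
#' @param samplesA,samplesB sample names/indices of the two groups.
#' @param class optional severity class restriction.
#' @param n_project haploid projection size; default `2 * min(|A|, |B|)`.
#' @return list with `matrix` ((n+1) x (n+1) expected counts, dimnames = derived
#'   copies 0..n in A and B), `n_project`, `n_sites`, `n_dropped`.
#' @export
jointSFS <- function(panel, samplesA, samplesB, class = NULL, n_project = NULL) {
  if (!polarized(panel)) stop("panel must be polarized")
  dA <- dosage(panel)[, samplesA, drop = FALSE]
  dB <- dosage(panel)[, samplesB, drop = FALSE]
  if (!is.null(class)) {
    sv <- severity(panel)
    rows <- !is.na(sv) & sv == class
    dA <- dA[rows, , drop = FALSE]
    dB <- dB[rows, , drop = FALSE]
  }
  if (nrow(dA) == 0) stop("no shared polarized sites for the two groups")
  if (is.null(n_project)) n_project <- 2L * min(ncol(dA), ncol(dB))
  n <- n_project
  kA <- rowSums(dA, na.rm = TRUE)
  mA <- 2L * rowSums(!is.na(dA))
  kB <- rowSums(dB, na.rm = TRUE)
  mB <- 2L * rowSums(!is.na(dB))
  ok <- mA >= n & mB >= n
  M <- matrix(0, n + 1, n + 1, dimnames = list(0:n, 0:n))
  for (i in which(ok)) {
    pA <- dhyper(0:n, kA[i], mA[i] - kA[i], n)
    pB <- dhyper(0:n, kB[i], mB[i] - kB[i], n)
    M <- M + outer(pA, pB)
  }
  list(matrix = M, n_project = n, n_sites = sum(ok), n_dropped = sum(!ok))
}

#' Asymmetry index of a joint SFS
#'
#' Quantifies how unevenly derived-allele frequencies are distributed between
#' two groups: `sum_{i<j} |M_ij - M_ji| / sum_{i!=j} M_ij`, after zeroing the
#' monomorphic corners (0,0) and (n,n). The index is 0 for a symmetric matrix
#' and 1 when all off-diagonal mass sits on one side.
#'
#' @param J a joint spectrum from [jointSFS()], or its matrix.
#' @return numeric in `[0, 1]`, or `NA` when there is no off-diagonal mass.
#' @export
asymmetryIndex <- function(J) {
  M <- if (is.list(J)) J$matrix else J
  n1 <- nrow(M)
  M[1, 1] <- 0
  M[n1, n1] <- 0
  off <- sum(M) - sum(diag(M))
  if (off == 0) {
    return(NA_real_)
  }
  sum(abs(M - t(M))[upper.tri(M)]) / off
}
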