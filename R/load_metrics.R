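#' Per-sample deleterious load by severity class
#'
#' Counts derived alleles per sample and severity class under the additive
#' mode (dosage sum: homozygous sites contribute 2, heterozygous 1) or the
#' recessive mode (one unit per homozygous-derived locus; `hom_units = 2`
#' counts two alleles per such locus instead). Missing genotypes are excluded
#' and reflected in `n_called`, so the per-called-site `rate` guards against
#' call-rate artifacts.
#'
#' The identity `additive - 2 * recessive = #het` holds per sample and class
#' (with the default `hom_units = 1`).
#'
#' @param panel a polarized, severity-annotated [GenoPanel-class].
#' @param mode `"additive"` or `"recessive"`.
#' @param classes severity classes to report (default: all present).
#' @param hom_units units per homozygous-derived locus in recessive mode.
#' @return data.frame with `sample_id`, `class`, `mode`, `count`, `n_called`,
#'   `rate`.
#' @export
sampleLoad <- function(panel, mode = c("additive", "recessive"),
                       classes = NULL, hom_units = 1L) {
  mode <- match.arg(mode)
  sv <- severity(panel)
  if (is.null(classes)) classes <- levels(droplevels(sv[!is.na(sv)]))
  d <- dosage(panel)
  ids <- colnames(d)
  if (is.null(ids)) ids <- paste0("sample", seq_len(ncol(d)))
  out <- lapply(classes, function(cl) {
    rows <- which(!is.na(sv) & sv == cl)
    dd <- d[rows, , drop = FALSE]
    n_called <- colSums(!is.na(dd))
    count <- if (mode == "additive") {
      colSums(dd, na.rm = TRUE)
    } else {
      hom_units * colSums(dd == 2L, na.rm = TRUE)
    }
    data.frame(
      sample_id = ids, class = cl, mode = mode,
      count = as.integer(count), n_called = as.integer(n_called),
      rate = ifelse(n_called > 0, count / n_called, NA_real_),
      row.names = NULL
    )
  })
  do.call(rbind, out)
}

#' Fixed deleterious load in a downsampled group
#'
#' Counts sites of each severity class whose derived allele frequency equals 1
#' in a random subsample of `target_n` accessions (frequency over non-missing
#' genotypes), matching the fixed-load protocol of downsampling each era to a
#' common size (30 for the Chinese eras, 74 for the US eras) before counting
#' alleles at frequency 1.
#'
#' @param panel polarized, severity-annotated [GenoPanel-class].
#' @param samples sample names/indices of the group.
#' @param target_n subsample size; the group must be at least this large.
#' @param seed integer seed making the subsample reproducible.
#' @param classes severity classes to report (default: all).
#' @return data.frame with `class`, `n_fixed`, `target_n`.
#' @export
fixedLoad <- function(panel, samples, target_n, seed = 1L, classes = NULL) {
  d <- dosage(panel)[, samples, drop = FALSE]
  if (ncol(d) < target_n) {
    stop(
      "group has ", ncol(d), " samples, fewer than target_n = ", target_n
    )
  }
  set.seed(seed)
  keep <- sample(ncol(d), target_n)
  d <- d[, keep, drop = FALSE]
  sv <- severity(panel)
  if (is.null(classes)) classes <- levels(droplevels(sv[!is.na(sv)]))
  called <- rowSums(!is.na(d))
  freq <- rowSums(d, na.rm = TRUE) / (2 * called)
  fixed <- called > 0 & freq == 1
  data.frame(
    class = classes,
    n_fixed = vapply(
      classes,
      function(cl) sum(fixed & !is.na(sv) & sv == cl), integer(1)
    ),
    target_n = target_n, row.names = NULL
  )
}

#' Compare per-sample loads between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test plus the percent change of
#' group means, `(mean_B - mean_A) / mean_A`.
#'
#' @param loadsA,loadsB numeric vectors of per-sample counts for two disjoint
#'   groups (each of size >= 2).
#' @param exact passed to [stats::wilcox.test()].
#' @return list with `U` (rank-sum statistic for `loadsA`), `p_value`,
#'   `pct_change`, `mean_A`, `mean_B`.
#' @export
compareGroupLoads <- function(loadsA, loadsB, exact = NULL) {
  if (length(loadsA) < 2 || length(loadsB) < 2) {
    stop("each group needs at least 2 samples")
  }
  wt <- wilcox.test(loadsA, loadsB, exact = exact)
  mA <- mean(loadsA)
  mB <- mean(loadsB)
  list(
    U = unname(wt$statistic), p_value = wt$p.value,
    pct_change = (mB - mA) / mA, mean_A = mA, mean_B = mB
  )
}
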