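#' Infer hybrid genotypes from parental inbred lines
#'
#' Hybrid dosage at a site is determined by the two parental genotypes:
#' both parents homozygous for the same allele gives that homozygote, parents
#' homozygous for different alleles gives a heterozygote, and any residual
#' parental heterozygosity or missingness yields a missing hybrid call (no
#' random gamete draw by default, since inbred lines are near-fully
#' homozygous). With `gamete_sampling = TRUE` a seeded random gamete is drawn
#' from heterozygous parents instead.
#'
#' @param panel [GenoPanel-class] of the parental lines.
#' @param pedigree data.frame with columns `hybrid_id`, `parent1`, `parent2`
#'   and optionally `year`.
#' @param gamete_sampling draw random gametes from heterozygous parents.
#' @param seed seed for gamete sampling.
#' @return a [GenoPanel-class] of hybrids on the same sites; `colData` carries
#'   `parent1`, `parent2`, `year` (if given) and `is_hybrid = TRUE`.
#' @export
inferHybrids <- function(panel, pedigree, gamete_sampling = FALSE, seed = 1L) {
  d <- dosage(panel)
  unknown <- setdiff(
    unique(c(pedigree$parent1, pedigree$parent2)),
    colnames(d)
  )
  if (length(unknown)) {
    stop("pedigree references unknown parent id(s): ", paste(unknown, collapse = ", "))
  }
  d1 <- d[, pedigree$parent1, drop = FALSE]
  d2 <- d[, pedigree$parent2, drop = FALSE]
  if (gamete_sampling) {
    set.seed(seed)
    draw <- function(x) {
      het <- !is.na(x) & x == 1L
      x[het] <- 2L * rbinom(sum(het), 1, 0.5)
      x
    }
    d1 <- draw(d1)
    d2 <- draw(d2)
  }
  hom1 <- !is.na(d1) & d1 != 1L
  hom2 <- !is.na(d2) & d2 != 1L
  hyb <- matrix(NA_integer_, nrow(d1), ncol(d1))
  ok <- hom1 & hom2
  hyb[ok] <- (d1[ok] + d2[ok]) %/% 2L
  colnames(hyb) <- pedigree$hybrid_id
  cd <- S4Vectors::DataFrame(
    parent1 = pedigree$parent1, parent2 = pedigree$parent2,
    is_hybrid = TRUE, row.names = pedigree$hybrid_id
  )
  if (!is.null(pedigree$year)) cd$year <- pedigree$year
  GenoPanel(hyb, SummarizedExperiment::rowRanges(panel),
    colData = cd, polarized = polarized(panel)
  )
}

#' Heterozygosity fraction of deleterious sites in hybrids
#'
#' Per hybrid and severity class: the fraction of derived-allele-carrying
#' sites that are heterozygous, `#{dosage = 1} / #{dosage >= 1}` (the
#' complementation measure). With `denominator = "segregating"` all called
#' class sites form the denominator instead. When a derived allele frequency
#' vector is supplied, fractions are additionally reported per DAF decile
#' ((0, 0.1], ..., (0.9, 1]); the `"all"` bin is always present.
#'
#' @param hybrids a hybrid [GenoPanel-class] (from [inferHybrids()]).
#' @param daf optional per-site derived allele frequency (computed on the
#'   parental panel via [derivedAlleleFreq()]).
#' @param bins number of DAF bins.
#' @param denominator `"carrying"` (sites with >= 1 derived allele) or
#'   `"segregating"` (all called sites of the class).
#' @return data.frame with `hybrid_id`, `class`, `daf_bin`, `numerator`,
#'   `denominator`, `fraction` (`NA` when the denominator is empty).
#' @export
hetFraction <- function(hybrids, daf = NULL, bins = 10L,
                        denominator = c("carrying", "segregating")) {
  denominator <- match.arg(denominator)
  sv <- severity(hybrids)
  d <- dosage(hybrids)
  ids <- colnames(d)
  bin_of <- if (is.null(daf)) {
    NULL
  } else {
    ifelse(is.na(daf) | daf <= 0, NA_integer_, pmin(bins, ceiling(daf * bins)))
  }
  classes <- levels(droplevels(sv[!is.na(sv)]))
  res <- list()
  for (cl in classes) {
    in_cl <- !is.na(sv) & sv == cl
    bin_sets <- list(all = in_cl)
    if (!is.null(bin_of)) {
      for (b in seq_len(bins)) {
        bin_sets[[as.character(b)]] <- in_cl & !is.na(bin_of) & bin_of == b
      }
    }
    for (bn in names(bin_sets)) {
      dd <- d[bin_sets[[bn]], , drop = FALSE]
      num <- colSums(dd == 1L, na.rm = TRUE)
      den <- if (denominator == "carrying") {
        colSums(dd >= 1L, na.rm = TRUE)
      } else {
        colSums(!is.na(dd))
      }
      res[[length(res) + 1L]] <- data.frame(
        hybrid_id = ids, class = cl, daf_bin = bn,
        numerator = as.integer(num), denominator = as.integer(den),
        fraction = ifelse(den > 0, num / den, NA_real_), row.names = NULL
      )
    }
  }
  do.call(rbind, res)
}

#' Paired t-test of heterozygosity fractions
#'
#' Two-sided paired t-test of per-hybrid heterozygosity fractions between a
#' deleterious class and the nondeleterious reference. Zero-variance,
#' nonzero-mean differences are reported as a degenerate result with
#' `t = +/-Inf` and `p = 0` rather than NaN.
#'
#' @param fracs_class,fracs_ref paired per-hybrid fractions (same hybrids,
#'   same order), length >= 3.
#' @return list with `t`, `p_value`, `mean_diff`, `degenerate`.
#' @export
pairedHetTest <- function(fracs_class, fracs_ref) {
  ok <- !is.na(fracs_class) & !is.na(fracs_ref)
  x <- fracs_class[ok] - fracs_ref[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) < 1e-10 * max(abs(mean(x)), 1)) {
    if (mean(x) == 0) {
      return(list(t = 0, p_value = 1, mean_diff = 0, degenerate = TRUE))
    }
    return(list(
      t = sign(mean(x)) * Inf, p_value = 0,
      mean_diff = mean(x), degenerate = TRUE
    ))
  }
  tt <- t.test(x)
  list(
    t = unname(tt$statistic), p_value = tt$p.value,
    mean_diff = mean(x), degenerate = FALSE
  )
}

#' Genome-wide correlation of deleterious and heterozygous density
#'
#' Tiles each chromosome with nonoverlapping windows (1 Mb by default, from
#' position 0) and correlates, across windows, the proportion of class
#' sites among all SNPs with the proportion of heterozygous genotype calls
#' among all non-missing calls in the hybrids. Both quantities are normalized
#' by the per-window SNP totals so windows of unequal density are comparable.
#'
#' @param hybrids hybrid [GenoPanel-class].
#' @param class severity class whose density forms the x variable.
#' @param window window size in bp.
#' @param min_snps minimum SNPs for a window to enter the correlation.
#' @return list with `windows` (data.frame chrom, start, end, n_snps, x, y),
#'   `pearson_r`, `p_value` (`NA` when either variable is constant).
#' @export
windowDensityCorrelation <- function(hybrids, class = "SLIGHT",
                                     window = 1e6, min_snps = 20L) {
  sv <- severity(hybrids)
  d <- dosage(hybrids)
  rr <- SummarizedExperiment::rowRanges(hybrids)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  win <- paste0(chrom, ":", floor((pos - 1) / window))
  het <- rowSums(d == 1L, na.rm = TRUE)
  called <- rowSums(!is.na(d))
  in_cl <- !is.na(sv) & sv == class

  agg <- function(v) tapply(v, win, sum)
  n_snps <- tapply(rep(1L, length(win)), win, sum)
  tab <- data.frame(
    key = names(n_snps), n_snps = as.integer(n_snps),
    x = as.numeric(agg(as.integer(in_cl))) / as.integer(n_snps),
    y = as.numeric(agg(het)) / as.numeric(agg(called)),
    row.names = NULL
  )
  parts <- strsplit(tab$key, ":", fixed = TRUE)
  tab$chrom <- vapply(parts, `[`, character(1), 1)
  tab$start <- as.numeric(vapply(parts, `[`, character(1), 2)) * window + 1
  tab$end <- tab$start + window - 1
  tab <- tab[order(tab$chrom, tab$start), c("chrom", "start", "end", "n_snps", "x", "y")]

  use <- tab$n_snps >= min_snps & is.finite(tab$y)
  if (sum(use) < 3) stop("fewer than 3 usable windows")
  if (sd(tab$x[use]) == 0 || sd(tab$y[use]) == 0) {
    return(list(windows = tab, pearson_r = NA_real_, p_value = NA_real_))
  }
  ct <- cor.test(tab$x[use], tab$y[use])
  list(windows = tab, pearson_r = unname(ct$estimate), p_value = ct$p.value)
}

#' Hypothetical hybrids from random parent pairs
#'
#' Draws `n` distinct unordered parent pairs uniformly at random (without
#' replacement across pairs) from the panel, the null counterpart of the
#' actual pedigree used to ask whether real crosses were chosen for better
#' complementation.
#'
#' @param panel parental [GenoPanel-class] (or a vector of parent ids).
#' @param n number of hypothetical crosses.
#' @param seed integer seed.
#' @return pedigree data.frame (`hybrid_id`, `parent1`, `parent2`).
#' @export
hypotheticalHybrids <- function(panel, n = 120L, seed = 1L) {
  ids <- if (is.character(panel)) panel else colnames(dosage(panel))
  if (length(ids) < 2) stop("need at least 2 parental lines")
  n_pairs <- choose(length(ids), 2)
  if (n > n_pairs) {
    stop("requested ", n, " crosses but only ", n_pairs, " distinct pairs exist")
  }
  set.seed(seed)
  all_pairs <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
  pick <- all_pairs[sample(n_pairs, n), , drop = FALSE]
  data.frame(
    hybrid_id = paste0("hypo", seq_len(n)),
    parent1 = ids[pick[, 1]], parent2 = ids[pick[, 2]], row.names = NULL
  )
}

#' Trend of hybrid load over release years
#'
#' Pearson correlation between per-hybrid deleterious load and hybrid release
#' year.
#'
#' @param loads numeric per-hybrid load counts.
#' @param years numeric release years, same length/order.
#' @return list with `pearson_r`, `p_value`, `n` (correlation `NA` when loads are
#'   constant).
#' @export
loadYearTrend <- function(loads, years) {
  ok <- !is.na(loads) & !is.na(years)
  if (sum(ok) < 3) stop("need at least 3 hybrids with years")
  x <- loads[ok]
  y <- years[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(pearson_r = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  ct <- cor.test(x, y)
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
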