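#' Midparent value
#'
#' Arithmetic mean of the two parental trait values; missing if either parent
#' is missing.
#'
#' @param trait_p1,trait_p2 numeric parental trait values (vectorized).
#' @return numeric midparent values.
#' @export
midparent <- function(trait_p1, trait_p2) {
  (trait_p1 + trait_p2) / 2
}

#' Percent heterosis
#'
#' Midparent heterosis on the relative scale:
#' `(F1 - midparent) / midparent`. Undefined (NA, with a warning) when the
#' midparent value is zero.
#'
#' @param f1 hybrid trait value(s).
#' @param mp midparent value(s).
#' @return numeric percent heterosis (as a proportion, 0.10 = 10%).
#' @export
percentHeterosis <- function(f1, mp) {
  out <- (f1 - mp) / mp
  zero <- !is.na(mp) & mp == 0
  if (any(zero)) {
    warning(sum(zero), " midparent value(s) are zero; percent heterosis undefined")
    out[zero] <- NA_real_
  }
  out
}

#' Heterosis table for a pedigree
#'
#' Joins hybrid and parental trait tables on a pedigree and computes the
#' midparent value, absolute heterosis (F1 - MP) and percent heterosis per
#' hybrid and trait.
#'
#' @param traits data.frame of trait values with a `sample_id` column covering
#'   both inbred parents and hybrids.
#' @param pedigree data.frame with `hybrid_id`, `parent1`, `parent2` and
#'   optionally `year`.
#' @param trait_cols trait column names (default: all numeric columns).
#' @return long data.frame: `hybrid_id`, `trait`, `f1`, `midparent`,
#'   `heterosis`, `pct_heterosis`, and `year` if present.
#' @export
heterosisTable <- function(traits, pedigree, trait_cols = NULL) {
  rownames(traits) <- traits$sample_id
  if (is.null(trait_cols)) {
    trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
    trait_cols <- setdiff(trait_cols, c("year"))
  }
  out <- lapply(trait_cols, function(tr) {
    f1 <- traits[pedigree$hybrid_id, tr]
    mp <- midparent(traits[pedigree$parent1, tr], traits[pedigree$parent2, tr])
    data.frame(
      hybrid_id = pedigree$hybrid_id, trait = tr, f1 = f1, midparent = mp,
      heterosis = f1 - mp,
      pct_heterosis = suppressWarnings(percentHeterosis(f1, mp)),
      row.names = NULL
    )
  })
  out <- do.call(rbind, out)
  if (!is.null(pedigree$year)) {
    out$year <- pedigree$year[match(out$hybrid_id, pedigree$hybrid_id)]
  }
  out
}

#' Trend of a quantity over years
#'
#' Least-squares slope against year with the Pearson correlation and its
#' two-sided p-value; the significance flag uses alpha = 0.01, the operative
#' threshold for era-trend claims in this analysis.
#'
#' @param values numeric values (trait, heterosis, load, ...).
#' @param years numeric years, same length.
#' @param alpha significance level for the `significant` flag.
#' @return list with `pearson_r`, `p_value`, `slope`, `n`, `significant`.
#' @export
trendTest <- function(values, years, alpha = 0.01) {
  ok <- !is.na(values) & !is.na(years)
  if (sum(ok) < 3) stop("need at least 3 (value, year) pairs")
  v <- values[ok]
  y <- years[ok]
  if (sd(y) == 0) stop("years are constant; trend undefined")
  slope <- unname(coef(lm(v ~ y))[2])
  if (sd(v) == 0) {
    return(list(
      pearson_r = NA_real_, p_value = NA_real_, slope = slope,
      n = sum(ok), significant = FALSE
    ))
  }
  ct <- cor.test(v, y)
  list(
    pearson_r = unname(ct$estimate), p_value = ct$p.value, slope = slope,
    n = sum(ok), significant = ct$p.value < alpha
  )
}
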