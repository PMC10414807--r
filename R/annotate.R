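#' Severity classification from conservation scores
#'
#' Sites are stratified by GERP score into `NONDEL` (gerp <= 0), `SLIGHT`
#' (0 < gerp <= 2), `MODERATE` (2 < gerp <= 4) and `STRONG` (gerp > 4).
#' Boundaries are half-open above, so 0, 2 and 4 fall in the lower class.
#'
#' @param gerp numeric vector of GERP scores; `NA` maps to `NA` class.
#' @return factor with levels `NONDEL < SLIGHT < MODERATE < STRONG`.
#' @examples
#' classifyGerp(c(-0.3, 1.5, 2, 4, 4.0001))
#' @export
classifyGerp <- function(gerp) {
  cut(gerp,
    breaks = c(-Inf, 0, 2, 4, Inf),
    labels = .SEVERITY_LEVELS, right = TRUE, ordered_result = TRUE
  )
}

#' SIFT-based deleterious call
#'
#' A site is SIFT-deleterious iff it is nonsynonymous and its SIFT score is
#' strictly below 0.05.
#'
#' @param sift numeric SIFT scores in `[0, 1]`.
#' @param is_nonsynonymous logical vector.
#' @return logical vector (`NA` where `sift` is missing).
#' @export
classifySift <- function(sift, is_nonsynonymous) {
  out <- is_nonsynonymous & sift < 0.05
  out[is.na(sift)] <- NA
  out
}

#' Polarize a panel to derived-allele dosage
#'
#' Uses the outgroup (ancestral) allele to orient each site: if the ancestral
#' allele equals REF the derived allele is ALT and dosages are kept; if it
#' equals ALT the derived allele is REF and dosages are flipped (2 <-> 0);
#' if it matches neither, or is missing, the site is excluded (a third-allele
#' outgroup state cannot be polarized). Exclusion is a normal outcome and is
#' reported via the `n_excluded` attribute.
#'
#' @param panel a ref/alt-oriented [GenoPanel-class] with an `ancestral`
#'   site column.
#' @param drop_excluded drop non-polarizable sites (default) or keep them with
#'   all-NA dosage and `excluded = TRUE` in the row data.
#' @return a polarized [GenoPanel-class] with `derived_allele` in the row data.
#' @export
polarizePanel <- function(panel, drop_excluded = TRUE) {
  if (polarized(panel)) {
    return(panel)
  }
  rd <- SummarizedExperiment::rowData(panel)
  if (is.null(rd$ancestral)) stop("panel has no 'ancestral' site column")
  anc <- as.character(rd$ancestral)
  ref <- as.character(rd$ref)
  alt <- as.character(rd$alt)

  status <- rep("excluded", nrow(panel))
  status[!is.na(anc) & anc == ref] <- "keep"
  status[!is.na(anc) & anc == alt] <- "flip"

  d <- dosage(panel)
  flip <- status == "flip"
  d[flip, ] <- 2L - d[flip, , drop = FALSE]
  excl <- status == "excluded"
  d[excl, ] <- NA_integer_

  rd$derived_allele <- ifelse(status == "keep", alt,
    ifelse(status == "flip", ref, NA_character_)
  )
  rd$excluded <- excl

  out <- panel
  SummarizedExperiment::assay(out, "dosage") <- d
  SummarizedExperiment::rowData(out) <- rd
  out@polarized <- TRUE
  if (drop_excluded) out <- out[!excl, ]
  attr(out, "n_excluded") <- sum(excl)
  out
}

#' Attach severity classes and SIFT calls to a panel
#'
#' Adds a `severity` factor column ([classifyGerp()]) and, when SIFT scores are
#' present, a `sift_deleterious` logical column ([classifySift()]).
#'
#' @param panel a [GenoPanel-class].
#' @return the panel with annotation columns added.
#' @export
annotateSeverity <- function(panel) {
  rd <- SummarizedExperiment::rowData(panel)
  if (is.null(rd$gerp)) stop("panel has no 'gerp' site column")
  rd$severity <- classifyGerp(rd$gerp)
  if (!is.null(rd$sift)) {
    ns <- if (is.null(rd$is_nonsynonymous)) rep(TRUE, nrow(panel)) else rd$is_nonsynonymous
    rd$sift_deleterious <- classifySift(rd$sift, ns)
  }
  SummarizedExperiment::rowData(panel) <- rd
  panel
}

#' Derived allele frequency per site
#'
#' @param panel a polarized [GenoPanel-class].
#' @param samples optional sample names/indices restricting the panel.
#' @return numeric vector of per-site derived allele frequencies over
#'   non-missing genotypes (`NaN` where no genotype is called).
#' @export
derivedAlleleFreq <- function(panel, samples = NULL) {
  if (!polarized(panel)) stop("panel must be polarized first (polarizePanel)")
  d <- dosage(panel)
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
}
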