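#' GenoPanel: a genotyped panel of inbred lines or hybrids
#'
#' `GenoPanel` extends [SummarizedExperiment::RangedSummarizedExperiment] with a
#' single `"dosage"` assay holding per-site allele counts in `{0, 1, 2, NA}`
#' (rows = sites, columns = samples). Row metadata carries the site annotation
#' (`ref`, `alt`, `ancestral`, `gerp`, `sift`, `is_nonsynonymous`, `is_genic`,
#' `is_synonymous` and, after [polarizePanel()] / [annotateSeverity()],
#' `derived_allele` and `severity`). Column metadata carries the sample sheet
#' (`era`, `heterotic_group`, `year`, `country`, `is_hybrid`).
#'
#' Dosage counts the ALT allele in a freshly read panel (ref/alt orientation)
#' and the derived allele after polarization; `polarized(x)` distinguishes the
#' two states.
#'
#' @slot polarized logical scalar; `TRUE` once dosages count derived alleles.
#'
#' @seealso [GenoPanel()] for construction, [readVcfPanel()], [polarizePanel()]
#' @export
setClass("GenoPanel",
  contains = "RangedSummarizedExperiment",
  slots = c(polarized = "logical"),
  prototype = prototype(polarized = FALSE)
)

setValidity("GenoPanel", function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  need <- c("ref", "alt")
  miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
  if (length(miss))
    msg <- c(msg, paste0("missing site columns: ", paste(miss, collapse = ", ")))
  if (length(object@polarized) != 1L)
    msg <- c(msg, "'polarized' must be a logical scalar")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenoPanel
#'
#' @param dosage integer/numeric matrix, sites x samples, values in
#'   `{0, 1, 2, NA}`.
#' @param rowRanges [GenomicRanges::GRanges] of site positions (width 1) with at
#'   least metadata columns `ref` and `alt`. Optional columns: `ancestral`,
#'   `gerp`, `sift`, `is_nonsynonymous`, `is_genic`, `is_synonymous`.
#' @param colData data.frame (or DataFrame) of sample metadata, one row per
#'   column of `dosage`.
#' @param polarized logical; whether dosages already count derived alleles.
#' @return A [GenoPanel-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 200), width = 1),
#'   ref = c("A", "G"), alt = c("T", "C")
#' )
#' gp <- GenoPanel(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'   dimnames = list(NULL, c("s1", "s2"))
#' ), gr, data.frame(row.names = c("s1", "s2")))
#' gp
#' @export
GenoPanel <- function(dosage, rowRanges, colData = NULL, polarized = FALSE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("sample", seq_len(ncol(dosage)))
  }
  if (is.null(colData)) {
    colData <- S4Vectors::DataFrame(row.names = colnames(dosage))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowRanges = rowRanges, colData = colData
  )
  new("GenoPanel", se, polarized = polarized)
}

#' @describeIn GenoPanel-class dosage matrix (sites x samples)
#' @param x,object a `GenoPanel`
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @export
setMethod("dosage", "GenoPanel", function(x) {
  SummarizedExperiment::assay(x, "dosage")
})

#' @describeIn GenoPanel-class has the panel been polarized to derived alleles?
#' @export
setGeneric("polarized", function(x) standardGeneric("polarized"))

#' @export
setMethod("polarized", "GenoPanel", function(x) x@polarized)

#' @describeIn GenoPanel-class site annotation as a data.frame with
#'   `chrom`/`pos` (1-based) prepended
#' @export
setGeneric("siteData", function(x) standardGeneric("siteData"))

#' @export
setMethod("siteData", "GenoPanel", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  cbind(
    data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(rr)),
      pos = GenomicRanges::start(rr)
    ),
    as.data.frame(S4Vectors::mcols(rr))
  )
})

#' @describeIn GenoPanel-class sample metadata as a data.frame
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @export
setMethod("sampleData", "GenoPanel", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @describeIn GenoPanel-class severity class factor (after
#'   [annotateSeverity()])
#' @export
setGeneric("severity", function(x) standardGeneric("severity"))

#' @export
setMethod("severity", "GenoPanel", function(x) {
  sv <- SummarizedExperiment::rowData(x)$severity
  if (is.null(sv)) stop("panel has no 'severity' column; run annotateSeverity()")
  sv
})

setMethod("show", "GenoPanel", function(object) {
  cat(
    "GenoPanel with", nrow(object), "sites x", ncol(object), "samples",
    if (object@polarized) "(derived-allele dosage)" else "(alt-allele dosage)",
    "\n"
  )
  sv <- SummarizedExperiment::rowData(object)$severity
  if (!is.null(sv)) {
    tab <- table(sv, useNA = "ifany")
    cat("severity:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  cd <- SummarizedExperiment::colData(object)
  if ("era" %in% colnames(cd)) {
    tab <- table(cd$era, useNA = "ifany")
    cat("eras:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(NULL)
})

# severity levels used throughout
.SEVERITY_LEVELS <- c("NONDEL", "SLIGHT", "MODERATE", "STRONG")
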