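#' Read a VCF into a GenoPanel
#'
#' Reads a VCF 4.x file, keeping biallelic SNP records only; multiallelic or
#' non-SNP records are skipped and counted (message + `n_skipped` attribute).
#' Per-site conservation score, ancestral allele and protein-impact score are
#' taken from INFO tags whose names are configurable.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param gerp_tag,aa_tag,sift_tag INFO tag names for the GERP score, the
#'   ancestral allele and the SIFT score.
#' @param nonsyn_tag INFO flag/tag marking nonsynonymous sites (value `1`/`0`
#'   or flag presence); optional.
#' @param sample_meta optional data.frame of sample metadata, row names (or an
#'   `id` column) matching VCF sample names.
#' @param require_tags character vector of tags that must be declared in the
#'   VCF header; a missing one raises a configuration error.
#' @return A [GenoPanel-class] in ref/alt orientation (dosage counts ALT
#'   alleles), with attribute `n_skipped`.
#' @export
readVcfPanel <- function(path, gerp_tag = "GERP", aa_tag = "AA",
                         sift_tag = "SIFT", nonsyn_tag = "NS",
                         sample_meta = NULL, require_tags = character()) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))

  meta <- vcf@meta
  for (tag in require_tags) {
    if (!any(grepl(paste0("##INFO=<ID=", tag, ","), meta, fixed = TRUE))) {
      stop("required INFO tag '", tag, "' is not declared in the VCF header")
    }
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE) & ref != alt
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    message("skipped ", n_skipped, " multiallelic or non-SNP record(s)")
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]

  # alt-allele dosage from GT strings; any missing allele -> NA
  parse_gt <- function(g) {
    g <- sub(":.*", "", g)
    a1 <- substr(g, 1, 1)
    a2 <- substr(g, 3, 3)
    out <- suppressWarnings(as.integer(a1) + as.integer(a2))
    out[a1 == "." | a2 == "." | is.na(g) | nchar(g) < 3] <- NA_integer_
    out
  }
  dos <- apply(gt, 2, parse_gt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(fix), dimnames = dimnames(gt))

  grab_info <- function(tag, numeric = TRUE) {
    val <- vcfR::extract.info(vcf, element = tag, as.numeric = numeric)
    val[snp]
  }
  gerp <- grab_info(gerp_tag)
  sift <- grab_info(sift_tag)
  aa <- grab_info(aa_tag, numeric = FALSE)
  ns <- grab_info(nonsyn_tag)

  rr <- GenomicRanges::GRanges(
    seqnames = fix[, "CHROM"],
    ranges = IRanges::IRanges(as.integer(fix[, "POS"]), width = 1L),
    ref = fix[, "REF"], alt = fix[, "ALT"], ancestral = aa,
    gerp = gerp, sift = sift,
    is_nonsynonymous = !is.na(ns) & ns == 1
  )

  cd <- NULL
  if (!is.null(sample_meta)) {
    if ("id" %in% colnames(sample_meta)) rownames(sample_meta) <- sample_meta$id
    cd <- sample_meta[colnames(dos), , drop = FALSE]
  }
  gp <- GenoPanel(dos, rr, colData = cd, polarized = FALSE)
  attr(gp, "n_skipped") <- n_skipped
  gp
}

#' Write a GenoPanel as VCF
#'
#' Emits an uncompressed VCF 4.2 file with `GERP`, `AA`, `SIFT` and `NS` INFO
#' tags and unphased diploid genotypes. Round-trips through [readVcfPanel()].
#'
#' @param panel a [GenoPanel-class] (ref/alt orientation).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVcfPanel <- function(panel, path) {
  sd <- siteData(panel)
  d <- dosage(panel)
  fmt_num <- function(x) ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE, scientific = FALSE))
  info_field <- function(i) {
    parts <- character()
    if (!is.null(sd$gerp) && !is.na(sd$gerp[i])) parts <- c(parts, paste0("GERP=", fmt_num(sd$gerp[i])))
    if (!is.null(sd$ancestral) && !is.na(sd$ancestral[i])) parts <- c(parts, paste0("AA=", sd$ancestral[i]))
    if (!is.null(sd$sift) && !is.na(sd$sift[i])) parts <- c(parts, paste0("SIFT=", fmt_num(sd$sift[i])))
    if (!is.null(sd$is_nonsynonymous) && isTRUE(sd$is_nonsynonymous[i])) parts <- c(parts, "NS=1")
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GERP,Number=1,Type=Float,Description=\"Conservation (rejected substitutions) score\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"SIFT score\">",
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Nonsynonymous site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(d)), function(i) {
    g <- d[i, ]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(sd$chrom[i], sd$pos[i], ".", sd$ref[i], sd$alt[i], ".", "PASS",
            info_field(i), "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genomic intervals (BED or GFF3)
#'
#' Thin wrapper over [rtracklayer::import()] returning a
#' [GenomicRanges::GRanges]. BED input (0-based half-open) and GFF3 input
#' (1-based inclusive) are both converted to the 1-based closed GRanges
#' convention, so the two representations of the same interval compare equal.
#'
#' @param path interval file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param feature for GFF3, restrict to this `type` (e.g. `"gene"`); `NULL`
#'   keeps everything.
#' @return `GRanges` with strand and, for GFF3, `ID`/`Name` metadata.
#' @export
readIntervals <- function(path, format = c("auto", "bed", "gff3"), feature = "gene") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3" && !is.null(feature) && "type" %in% colnames(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) %in% feature]
  }
  if (any(GenomicRanges::width(gr) < 1L)) {
    stop("interval with end < start after conversion in ", path)
  }
  gr
}

#' Read / write tab-separated tables with "." for missing
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `readTsv`: a data.frame; `writeTsv`: `path` invisibly.
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  read.table(path,
    header = TRUE, sep = "\t", na.strings = ".",
    stringsAsFactors = FALSE, check.names = FALSE, comment.char = ""
  )
}

#' @rdname readTsv
#' @export
writeTsv <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.numeric(x[[j]]) && !is.integer(x[[j]])) {
      x[[j]] <- ifelse(is.na(x[[j]]), NA,
        format(x[[j]], digits = 15, trim = TRUE, scientific = FALSE)
      )
    }
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}
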