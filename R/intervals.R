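#' Gene body, promoter and combined regions
#'
#' Builds, for each gene, the gene body, the 2-kb upstream promoter
#' (strand-aware, clipped at the chromosome boundary) and their union. The
#' promoter abuts the 5' end of the body.
#'
#' @param genes [GenomicRanges::GRanges] of gene bodies with strand and a
#'   `gene_id` (or `ID`) metadata column.
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param promoter_width promoter length in bp.
#' @return list of `GRanges` (`body`, `promoter`, `combined`), parallel to
#'   `genes`, each with a `gene_id` column.
#' @export
buildGeneRegions <- function(genes, chrom_sizes, promoter_width = 2000L) {
  ids <- genes$gene_id
  if (is.null(ids)) ids <- genes$ID
  if (is.null(ids)) ids <- paste0("gene", seq_along(genes))
  sizes <- chrom_sizes[as.character(GenomeInfoDb::seqnames(genes))]
  if (any(is.na(sizes))) stop("chrom_sizes is missing a chromosome present in 'genes'")
  if (any(GenomicRanges::start(genes) < 1) || any(GenomicRanges::end(genes) > sizes)) {
    stop("gene interval outside chromosome bounds")
  }
  body <- genes
  S4Vectors::mcols(body) <- NULL
  body$gene_id <- ids
  prom <- GenomicRanges::promoters(body, upstream = promoter_width, downstream = 0)
  GenomicRanges::start(prom) <- pmax(GenomicRanges::start(prom), 1L)
  GenomicRanges::end(prom) <- pmin(GenomicRanges::end(prom), as.integer(sizes))
  comb <- GenomicRanges::punion(body, prom)
  comb$gene_id <- ids
  list(body = body, promoter = prom, combined = comb)
}

#' Count sites per gene region and severity class
#'
#' Interval membership of variant sites in the promoter, body and combined
#' region of each gene. A site overlapping the regions of several genes is
#' counted once per gene-region.
#'
#' @param sites [GenomicRanges::GRanges] of variant positions (width 1).
#' @param regions result of [buildGeneRegions()].
#' @param classes optional factor over `sites` (e.g. severity); counts are
#'   reported per level. `NULL` counts all sites as one class `"all"`.
#' @return data.frame: `gene_id`, `class`, `promoter`, `body`, `combined`.
#' @export
countInRegions <- function(sites, regions, classes = NULL) {
  if (is.null(classes)) {
    classes <- factor(rep("all", length(sites)), levels = "all")
  } else {
    classes <- droplevels(as.factor(classes))
  }
  out <- lapply(levels(classes), function(cl) {
    s <- sites[!is.na(classes) & classes == cl]
    data.frame(
      gene_id = regions$body$gene_id, class = cl,
      promoter = GenomicRanges::countOverlaps(regions$promoter, s),
      body = GenomicRanges::countOverlaps(regions$body, s),
      combined = GenomicRanges::countOverlaps(regions$combined, s),
      row.names = NULL
    )
  })
  do.call(rbind, out)
}

#' Deleterious-count contrast between DEGs and non-DEGs
#'
#' Rank-sum tests of per-gene deleterious site counts between differentially
#' and non-differentially expressed genes, for the promoter, gene body and
#' combined region; run separately on nondeleterious counts as a negative
#' control for overall-diversity differences. Optionally also contrasts the
#' per-gene heterozygous fraction of deleterious sites in hybrids between the
#' two gene sets.
#'
#' @param counts output of [countInRegions()] with a deleterious and
#'   (optionally) a nondeleterious class.
#' @param deg_labels data.frame with `gene_id` and logical `is_deg`.
#' @param deleterious_classes,control_classes class labels pooled as
#'   "deleterious" and as the nondeleterious control.
#' @param hybrids optional hybrid [GenoPanel-class] for the heterozygosity
#'   contrast; `regions` must then be supplied.
#' @param regions regions from [buildGeneRegions()] (combined region used).
#' @return list of per-region test results (`wilcox_p`, group medians), a
#'   `control` element with the nondeleterious contrast, and `het_contrast`
#'   when hybrids are given.
#' @export
degContrast <- function(counts, deg_labels,
                        deleterious_classes = c("SLIGHT", "MODERATE", "STRONG"),
                        control_classes = "NONDEL",
                        hybrids = NULL, regions = NULL) {
  lab <- deg_labels$is_deg[match(counts$gene_id, deg_labels$gene_id)]
  if (all(lab, na.rm = TRUE) || !any(lab, na.rm = TRUE)) {
    stop("both DEG and non-DEG labels are required")
  }
  one <- function(cls) {
    keep <- counts$class %in% cls
    agg <- stats::aggregate(
      counts[keep, c("promoter", "body", "combined")],
      by = list(gene_id = counts$gene_id[keep]), FUN = sum
    )
    is_deg <- deg_labels$is_deg[match(agg$gene_id, deg_labels$gene_id)]
    lapply(c(promoter = "promoter", body = "body", combined = "combined"), function(rg) {
      x <- agg[[rg]][is_deg]
      y <- agg[[rg]][!is_deg]
      if (length(x) < 2 || length(y) < 2) stop("need >= 2 genes per label")
      wt <- suppressWarnings(wilcox.test(x, y))
      list(
        wilcox_p = wt$p.value, median_deg = median(x), median_nondeg = median(y)
      )
    })
  }
  out <- one(deleterious_classes)
  out$control <- one(control_classes)
  if (!is.null(hybrids)) {
    if (is.null(regions)) stop("'regions' is required for the heterozygosity contrast")
    out$het_contrast <- .deg_het_contrast(
      hybrids, regions, deg_labels, deleterious_classes
    )
  }
  out
}

# per-gene heterozygous fraction of deleterious sites across hybrids
.deg_het_contrast <- function(hybrids, regions, deg_labels, deleterious_classes) {
  sv <- severity(hybrids)
  del <- !is.na(sv) & sv %in% deleterious_classes
  rr <- SummarizedExperiment::rowRanges(hybrids)[del]
  d <- dosage(hybrids)[del, , drop = FALSE]
  ov <- GenomicRanges::findOverlaps(regions$combined, rr)
  het_site <- rowSums(d == 1L, na.rm = TRUE)
  car_site <- rowSums(d >= 1L, na.rm = TRUE)
  num <- tapply(het_site[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov), sum)
  den <- tapply(car_site[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov), sum)
  frac <- rep(NA_real_, length(regions$combined))
  frac[as.integer(names(num))] <- as.numeric(num) / pmax(1, as.numeric(den))
  is_deg <- deg_labels$is_deg[match(regions$combined$gene_id, deg_labels$gene_id)]
  x <- frac[is_deg & !is.na(frac)]
  y <- frac[!is_deg & !is.na(frac)]
  wt <- suppressWarnings(wilcox.test(x, y))
  list(
    wilcox_p = wt$p.value, median_deg = median(x), median_nondeg = median(y)
  )
}

#' QTL enrichment of deleterious sites
#'
#' One-proportion Z test of the fraction of deleterious sites inside QTL
#' intervals against the nondeleterious fraction as the null proportion,
#' `Z = (p_hat - p0) / sqrt(p0 (1 - p0) / n_del)`; plus a Pearson chi-square
#' test (no continuity correction by default) on the 2x2 table of deleterious
#' versus synonymous-nondeleterious sites inside/outside QTL, which guards
#' against the genic-location bias of deleterious sites. Per-class Z scores
#' are reported when a class factor is given.
#'
#' @param del_sites,nondel_sites `GRanges` of deleterious and nondeleterious
#'   site positions.
#' @param qtl `GRanges` of QTL intervals.
#' @param syn_sites synonymous nondeleterious sites for the chi-square
#'   contrast (defaults to `nondel_sites`).
#' @param del_classes optional factor over `del_sites` for per-class Z.
#' @param correct continuity correction for the chi-square test.
#' @return list with `z`, `z_p`, `p_hat`, `p0`, `chisq`, `chisq_p`, `table`,
#'   and `per_class` (data.frame) when classes are given. `z` is `NA` when
#'   the null proportion is degenerate (0 or 1).
#' @export
qtlEnrichment <- function(del_sites, nondel_sites, qtl, syn_sites = NULL,
                          del_classes = NULL, correct = FALSE) {
  if (!length(del_sites) || !length(nondel_sites)) {
    stop("both deleterious and reference site sets must be non-empty")
  }
  in_qtl <- function(s) GenomicRanges::countOverlaps(s, qtl) > 0
  zstat <- function(s) {
    hit <- in_qtl(s)
    p_hat <- mean(hit)
    if (p0 %in% c(0, 1)) {
      return(c(z = NA_real_, p = NA_real_, p_hat = p_hat))
    }
    z <- (p_hat - p0) / sqrt(p0 * (1 - p0) / length(s))
    c(z = z, p = 2 * pnorm(-abs(z)), p_hat = p_hat)
  }
  p0 <- mean(in_qtl(nondel_sites))
  zs <- zstat(del_sites)

  if (is.null(syn_sites)) syn_sites <- nondel_sites
  tab <- rbind(
    deleterious = c(inside = sum(in_qtl(del_sites)), outside = sum(!in_qtl(del_sites))),
    synonymous = c(inside = sum(in_qtl(syn_sites)), outside = sum(!in_qtl(syn_sites)))
  )
  cs <- suppressWarnings(chisq.test(tab, correct = correct))
  out <- list(
    z = unname(zs["z"]), z_p = unname(zs["p"]), p_hat = unname(zs["p_hat"]),
    p0 = p0, chisq = unname(cs$statistic), chisq_p = cs$p.value, table = tab
  )
  if (!is.null(del_classes)) {
    del_classes <- droplevels(as.factor(del_classes))
    out$per_class <- do.call(rbind, lapply(levels(del_classes), function(cl) {
      z <- zstat(del_sites[del_classes == cl])
      data.frame(class = cl, z = unname(z["z"]), p = unname(z["p"]), row.names = NULL)
    }))
  }
  out
}

#' Genotype-phenotype-expression contrast at a candidate locus
#'
#' Compares trait values and (optionally) expression of the closest gene
#' between lines homozygous for the derived allele and lines homozygous for
#' the ancestral allele at one site; heterozygotes are excluded.
#'
#' @param site_dosage per-sample derived dosage at the locus `{0, 1, 2, NA}`.
#' @param trait per-sample trait values.
#' @param expression optional per-sample expression values.
#' @param min_n minimum lines per homozygote class.
#' @return list with `trait_p`, `expression_p`, group sizes and medians.
#' @export
candidateContrast <- function(site_dosage, trait, expression = NULL, min_n = 2L) {
  hom_der <- !is.na(site_dosage) & site_dosage == 2L
  hom_anc <- !is.na(site_dosage) & site_dosage == 0L
  if (sum(hom_der) < min_n || sum(hom_anc) < min_n) {
    stop(
      "need at least ", min_n, " lines per homozygote class (derived: ",
      sum(hom_der), ", ancestral: ", sum(hom_anc), ")"
    )
  }
  wt <- suppressWarnings(wilcox.test(trait[hom_der], trait[hom_anc]))
  out <- list(
    trait_p = wt$p.value,
    n_derived = sum(hom_der), n_ancestral = sum(hom_anc),
    trait_median_derived = median(trait[hom_der], na.rm = TRUE),
    trait_median_ancestral = median(trait[hom_anc], na.rm = TRUE)
  )
  if (!is.null(expression)) {
    we <- suppressWarnings(wilcox.test(expression[hom_der], expression[hom_anc]))
    out$expression_p <- we$p.value
    out$expression_median_derived <- median(expression[hom_der], na.rm = TRUE)
    out$expression_median_ancestral <- median(expression[hom_anc], na.rm = TRUE)
  }
  out
}
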