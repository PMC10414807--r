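#' Configuration for the synthetic breeding-panel generator
#'
#' Defaults emulate the study conditions of an elite maize panel: five era
#' groups on one chronological timeline with sample sizes 30 (CN_1960&70s),
#' 74 (Public_US), 95 (CN_1980&90s), 89 (Ex-PVP) and 53 (CN_2000&10s); four
#' heterotic groups (SS, NSS, IDT, HZS) diverging by drift from a common
#' ancestral pool; per-group effective size shrinking 500 -> 50 and selfing
#' rising 0.5 -> 0.95 across eras; purifying selection growing with severity
#' class (s = 0, 0.001, 0.02, 0.1) with dominance h = 0.25 so deleterious
#' alleles are partially recessive and complementation can act.
#'
#' @param n_sites number of segregating sites on the single chromosome.
#' @param chrom_length chromosome length in bp.
#' @param severity_mix named proportions over NONDEL/SLIGHT/MODERATE/STRONG.
#' @param s_map named per-class selection coefficients.
#' @param h dominance coefficient of deleterious alleles.
#' @param era_schedule data.frame with `label`, `Ne` (per heterotic group),
#'   `generations`, `selfing`, `sample_n`, `year`, `country`, in
#'   chronological order.
#' @param n_groups number of heterotic groups.
#' @param hybrid_n default number of crosses for [makeCrosses()].
#' @param recomb_morgans genetic map length of the chromosome (Morgans).
#' @param mismatch_rate fraction of sites whose recorded outgroup allele is a
#'   third base, exercising the polarization-exclusion path.
#' @param init_freq range of initial derived allele frequencies for
#'   nondeleterious sites (standing neutral variation).
#' @param init_freq_deleterious range for deleterious classes that are shared
#'   across groups (mutation-selection-balance frequencies).
#' @param deleterious_private_frac fraction of deleterious sites that start
#'   restricted to one heterotic group. The divergence of the breeding pools
#'   predates the simulated breeding timeline, so the initial state already
#'   carries group-private deleterious variants; this is what lets
#'   between-group hybrids complement them while within-group crosses do not.
#' @param init_freq_private frequency range of a private deleterious variant
#'   inside its home group (zero elsewhere).
#' @param group_load_weights relative share of private deleterious variants
#'   homed in each heterotic group. Breeding pools do not carry equal
#'   deleterious burdens (the SS pool, source of the most intensively
#'   selected lines, carries the least), and this imbalance is what makes
#'   the joint SFS between two pools visibly asymmetric.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
simConfig <- function(n_sites = 800L,
                      chrom_length = 1e7,
                      severity_mix = c(NONDEL = 0.55, SLIGHT = 0.25, MODERATE = 0.12, STRONG = 0.08),
                      s_map = c(NONDEL = 0, SLIGHT = 0.001, MODERATE = 0.02, STRONG = 0.1),
                      h = 0.25,
                      era_schedule = data.frame(
                        label = c("CN_1960&70s", "Public_US", "CN_1980&90s", "Ex-PVP", "CN_2000&10s"),
                        Ne = c(500L, 350L, 200L, 100L, 50L),
                        generations = c(25L, 15L, 15L, 15L, 15L),
                        selfing = c(0.5, 0.6, 0.7, 0.85, 0.95),
                        sample_n = c(30L, 74L, 95L, 89L, 53L),
                        year = c(1965, 1980, 1990, 2003, 2010),
                        country = c("CN", "US", "CN", "US", "CN")
                      ),
                      n_groups = 4L,
                      hybrid_n = 120L,
                      recomb_morgans = 2,
                      mismatch_rate = 0.05,
                      init_freq = c(0.05, 0.5),
                      init_freq_deleterious = c(0.01, 0.15),
                      deleterious_private_frac = 0.7,
                      init_freq_private = c(0.1, 0.9),
                      group_load_weights = c(SS = 0.1, NSS = 0.2, IDT = 0.3, HZS = 0.4),
                      seed = 1L) {
  stopifnot(abs(sum(severity_mix) - 1) < 1e-8)
  if (any(era_schedule$selfing < 0 | era_schedule$selfing > 1)) {
    stop("selfing rates must lie in [0, 1]")
  }
  if (any(era_schedule$Ne * n_groups < era_schedule$sample_n)) {
    stop("total population (Ne x n_groups) must cover sample_n in every era")
  }
  if (all(s_map >= 1)) stop("infeasible config: all genotypes have fitness <= 0")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a panel of inbred lines across breeding eras
#'
#' Forward Wright-Fisher simulation with partial selfing on one recombining
#' chromosome. Each generation, every offspring selfs with the era's selfing
#' probability or draws two parents by fitness-weighted sampling; fitness is
#' multiplicative across sites with per-genotype fitness 1, 1 - hs, 1 - s for
#' 0/1/2 derived copies. Heterotic groups evolve independently from a shared
#' ancestral frequency vector (split at generation 0); each era is sampled at
#' the end of its scheduled generations, spreading `sample_n` accessions
#' across the groups. GERP scores are drawn per severity class (NONDEL
#' U(-3,0], SLIGHT U(0,2], MODERATE U(2,4], STRONG U(4,8]); the recorded
#' outgroup allele equals the true ancestral allele except for a
#' `mismatch_rate` fraction set to a third base.
#'
#' The returned panel is in ref/alt orientation with an `AA` ancestral
#' column, ready for [polarizePanel()] + [annotateSeverity()]; the element
#' `truth` carries the generating values for recovery tests.
#'
#' @param config a [simConfig()] list.
#' @return list with `panel` (a [GenoPanel-class] of all era samples),
#'   `genes` (GRanges of simulated gene models) and `truth` (per-site class,
#'   selection coefficients, true derived dosage matrix, per-era derived
#'   allele frequencies).
#' @export
simulateILs <- function(config = simConfig()) {
  set.seed(config$seed)
  L <- config$n_sites
  pos <- sort(sample.int(config$chrom_length - 1L, L))
  cls <- factor(
    sample(.SEVERITY_LEVELS, L, replace = TRUE, prob = config$severity_mix),
    levels = .SEVERITY_LEVELS
  )
  gerp_rng <- list(
    NONDEL = c(-3, 0), SLIGHT = c(0, 2), MODERATE = c(2, 4), STRONG = c(4, 8)
  )
  gerp <- vapply(seq_len(L), function(i) {
    r <- gerp_rng[[as.character(cls[i])]]
    runif(1, r[1], r[2])
  }, numeric(1))
  s <- unname(config$s_map[as.character(cls)])
  h <- config$h
  rec <- config$recomb_morgans / (L - 1)
  G <- config$n_groups
  # per-group initial frequencies: neutral standing variation is shared;
  # deleterious variants are either shared at mutation-selection-balance
  # frequencies or private to one home group (pool divergence predating the
  # simulated timeline)
  q0 <- runif(L, config$init_freq[1], config$init_freq[2])
  del <- cls != "NONDEL"
  q0[del] <- runif(
    sum(del), config$init_freq_deleterious[1], config$init_freq_deleterious[2]
  )
  q0g <- matrix(rep(q0, each = G), G, L)
  private <- del & runif(L) < config$deleterious_private_frac
  w_home <- config$group_load_weights[seq_len(G)]
  home <- sample.int(G, L, replace = TRUE, prob = w_home / sum(w_home))
  for (j in which(private)) {
    q0g[, j] <- 0
    q0g[home[j], j] <- runif(
      1, config$init_freq_private[1], config$init_freq_private[2]
    )
  }

  genes <- simulateGenes(
    n_genes = max(50L, round(L / 4)), chrom_length = config$chrom_length,
    seed = config$seed + 1L
  )
  set.seed(config$seed + 2L)

  sched <- config$era_schedule
  grp_names <- c("SS", "NSS", "IDT", "HZS")[seq_len(G)]
  pops <- lapply(seq_len(G), function(g) {
    N <- sched$Ne[1]
    list(
      H1 = matrix(rbinom(N * L, 1L, rep(q0g[g, ], each = N)), N, L),
      H2 = matrix(rbinom(N * L, 1L, rep(q0g[g, ], each = N)), N, L)
    )
  })

  sel_idx <- which(s > 0)
  log_hs <- log1p(-h * s[sel_idx])
  log_s <- log1p(-s[sel_idx])
  fitness <- function(pop) {
    Gm <- pop$H1[, sel_idx, drop = FALSE] + pop$H2[, sel_idx, drop = FALSE]
    lw <- (Gm == 1L) %*% log_hs + (Gm == 2L) %*% log_s
    w <- exp(lw - max(lw))
    if (all(w == 0)) stop("infeasible config: population fitness collapsed to 0")
    drop(w)
  }

  samples <- list()
  era_freq <- matrix(NA_real_, nrow(sched), L, dimnames = list(sched$label, NULL))
  for (e in seq_len(nrow(sched))) {
    for (gen in seq_len(sched$generations[e])) {
      N_next <- sched$Ne[e]
      for (g in seq_len(G)) {
        w <- fitness(pops[[g]])
        p1 <- sample.int(length(w), N_next, replace = TRUE, prob = w)
        selfed <- runif(N_next) < sched$selfing[e]
        p2 <- ifelse(selfed, p1, sample.int(length(w), N_next, replace = TRUE, prob = w))
        nxt <- .wf_generation(
          pops[[g]]$H1, pops[[g]]$H2,
          as.integer(p1 - 1L), as.integer(p2 - 1L), rec
        )
        pops[[g]] <- nxt
      }
    }
    # sample accessions for this era, spread across groups
    per_grp <- rep(sched$sample_n[e] %/% G, G)
    extra <- sched$sample_n[e] %% G
    if (extra > 0) per_grp[seq_len(extra)] <- per_grp[seq_len(extra)] + 1L
    for (g in seq_len(G)) {
      take <- sample.int(nrow(pops[[g]]$H1), per_grp[g])
      dos <- t(pops[[g]]$H1[take, , drop = FALSE] + pops[[g]]$H2[take, , drop = FALSE])
      samples[[length(samples) + 1L]] <- list(
        dosage = dos, era = sched$label[e], group = grp_names[g],
        year = sched$year[e], country = sched$country[e]
      )
    }
    dall <- do.call(cbind, lapply(
      samples[(length(samples) - G + 1L):length(samples)],
      function(x) x$dosage
    ))
    era_freq[e, ] <- rowMeans(dall) / 2
  }

  derived_dos <- do.call(cbind, lapply(samples, function(x) x$dosage))
  n_tot <- ncol(derived_dos)
  ids <- sprintf("IL%03d", seq_len(n_tot))
  colnames(derived_dos) <- ids
  meta <- do.call(rbind, lapply(samples, function(x) {
    data.frame(
      era = x$era, heterotic_group = x$group, year = x$year,
      country = x$country, n = ncol(x$dosage)
    )
  }))
  cd <- S4Vectors::DataFrame(
    era = rep(meta$era, meta$n),
    heterotic_group = rep(meta$heterotic_group, meta$n),
    year = rep(meta$year, meta$n),
    country = rep(meta$country, meta$n),
    is_hybrid = FALSE, row.names = ids
  )

  # emit in ref/alt orientation: ancestral allele is REF for half the sites
  bases <- c("A", "C", "G", "T")
  anc_base <- sample(bases, L, replace = TRUE)
  der_base <- vapply(anc_base, function(b) sample(setdiff(bases, b), 1), character(1))
  anc_is_ref <- runif(L) < 0.5
  ref <- ifelse(anc_is_ref, anc_base, der_base)
  alt <- ifelse(anc_is_ref, der_base, anc_base)
  alt_dos <- derived_dos
  alt_dos[!anc_is_ref, ] <- 2L - alt_dos[!anc_is_ref, , drop = FALSE]
  recorded_anc <- anc_base
  mm <- runif(L) < config$mismatch_rate
  recorded_anc[mm] <- vapply(
    which(mm),
    function(i) sample(setdiff(bases, c(ref[i], alt[i])), 1), character(1)
  )

  gr_sites <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pos, width = 1L),
    ref = ref, alt = alt, ancestral = recorded_anc, gerp = gerp
  )
  in_gene <- GenomicRanges::countOverlaps(
    gr_sites, genes
  ) > 0
  gr_sites$is_genic <- in_gene
  nonsyn <- in_gene & runif(L) < 0.3
  gr_sites$is_nonsynonymous <- nonsyn
  gr_sites$is_synonymous <- in_gene & !nonsyn
  sift <- rep(NA_real_, L)
  ns_idx <- which(nonsyn)
  sift[ns_idx] <- runif(length(ns_idx))
  del_ns <- ns_idx[cls[ns_idx] != "NONDEL"]
  sift[del_ns] <- rbeta(length(del_ns), 0.5, 5)
  gr_sites$sift <- sift
  GenomeInfoDb::seqlengths(gr_sites) <- c(chr1 = config$chrom_length)

  panel <- GenoPanel(alt_dos, gr_sites, colData = cd, polarized = FALSE)
  list(
    panel = panel, genes = genes,
    truth = list(
      class = cls, s = s, gerp = gerp, q0 = q0, q0_group = q0g,
      private = private, home_group = home, era_freq = era_freq,
      derived_dosage = derived_dos, anc_is_ref = anc_is_ref,
      outgroup_mismatch = mm
    )
  )
}

#' Simulated gene models
#'
#' Uniformly placed non-overlapping genes with random strand on one
#' chromosome.
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length (bp).
#' @param gene_length min/max gene length (bp).
#' @param seed integer seed.
#' @return `GRanges` with `gene_id` and strand.
#' @export
simulateGenes <- function(n_genes = 200L, chrom_length = 1e7,
                          gene_length = c(2000L, 6000L), seed = 1L) {
  set.seed(seed)
  slot_w <- floor(chrom_length / n_genes)
  if (slot_w <= gene_length[2] + 4000) {
    stop("chromosome too short for ", n_genes, " non-overlapping genes")
  }
  len <- sample(gene_length[1]:gene_length[2], n_genes, replace = TRUE)
  start <- (seq_len(n_genes) - 1L) * slot_w +
    sample(2001:(slot_w - gene_length[2] - 2000), n_genes, replace = TRUE)
  GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start, width = len),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    seqlengths = c(chr1 = chrom_length)
  )
}

#' Random crosses between (or within) heterotic groups
#'
#' Draws `hybrid_n` distinct unordered parent pairs; by default the two
#' parents must come from different heterotic groups, with
#' `within_group = TRUE` they must share one. The hybrid release year is the
#' later parent's era year plus a small jitter.
#'
#' @param panel an IL [GenoPanel-class] whose `colData` has
#'   `heterotic_group` and `year`.
#' @param hybrid_n number of crosses.
#' @param within_group cross within rather than between groups.
#' @param seed integer seed.
#' @return pedigree data.frame: `hybrid_id`, `parent1`, `parent2`, `year`.
#' @export
makeCrosses <- function(panel, hybrid_n = 120L, within_group = FALSE, seed = 1L) {
  cd <- sampleData(panel)
  ids <- rownames(cd)
  grp <- cd$heterotic_group
  if (!within_group && length(unique(grp)) < 2) {
    stop("between-group crosses need at least 2 heterotic groups")
  }
  pairs <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
  okay <- if (within_group) {
    grp[pairs[, 1]] == grp[pairs[, 2]]
  } else {
    grp[pairs[, 1]] != grp[pairs[, 2]]
  }
  pairs <- pairs[okay, , drop = FALSE]
  if (hybrid_n > nrow(pairs)) {
    stop("insufficient parents: only ", nrow(pairs), " eligible pairs")
  }
  if (hybrid_n == 0) {
    return(data.frame(
      hybrid_id = character(), parent1 = character(),
      parent2 = character(), year = numeric()
    ))
  }
  set.seed(seed)
  pick <- pairs[sample.int(nrow(pairs), hybrid_n), , drop = FALSE]
  year <- pmax(cd$year[pick[, 1]], cd$year[pick[, 2]]) +
    sample(0:3, hybrid_n, replace = TRUE)
  data.frame(
    hybrid_id = sprintf("HYB%03d", seq_len(hybrid_n)),
    parent1 = ids[pick[, 1]], parent2 = ids[pick[, 2]],
    year = year, row.names = NULL
  )
}

#' Simulate a quantitative trait on a genotyped panel
#'
#' Additive-plus-dominance architecture:
#' `y = sum_j a_j x_j + sum_j d_j 1[x_j = 1] + e`, with causal additive
#' effects `a_j ~ N(0, (2 p_j q_j)^S_coupling)`, `|a_j|` inflated by
#' `deleterious_inflation` for deleterious classes, and `d_j = k_j a_j`
#' with `k_j ~ U(0, 1)`. Effects and the noise are rescaled so the realized
#' additive and dominance variance fractions hit the targets.
#'
#' @param X dosage matrix (samples x markers) or [GenoPanel-class].
#' @param classes optional per-marker severity factor (for the inflation).
#' @param h2_A,h2_D target additive and dominance variance fractions
#'   (`h2_A + h2_D < 1`).
#' @param S_coupling exponent coupling effect variance to `2pq`.
#' @param deleterious_inflation multiplier on `|a|` for non-NONDEL classes.
#' @param frac_causal fraction of polymorphic markers with nonzero effects.
#' @param seed integer seed.
#' @return list with `y` (named by sample), `effects` (data.frame `marker`,
#'   `a`, `d`, `causal`), realized `h2_A`, `h2_D`.
#' @export
simulatePhenotypes <- function(X, classes = NULL, h2_A = 0.5, h2_D = 0.1,
                               S_coupling = 0, deleterious_inflation = 1,
                               frac_causal = 1, seed = 1L) {
  if (h2_A + h2_D >= 1) stop("h2_A + h2_D must be < 1")
  X <- .as_sample_matrix(X)
  set.seed(seed)
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  m <- ncol(X)
  causal <- poly & runif(m) < frac_causal
  v2pq <- 2 * p * (1 - p)
  a <- rep(0, m)
  a[causal] <- rnorm(sum(causal), 0, sqrt(v2pq[causal]^S_coupling))
  if (!is.null(classes) && deleterious_inflation != 1) {
    del <- causal & !is.na(classes) & classes != "NONDEL"
    a[del] <- a[del] * deleterious_inflation
  }
  k <- runif(m)
  d <- k * a
  Ximp <- X
  Ximp[is.na(Ximp)] <- 0
  gA <- drop(Ximp %*% a)
  gD <- drop((Ximp == 1) %*% d)
  vA <- var(gA)
  vD <- var(gD)
  lamA <- if (h2_A > 0 && vA > 0) sqrt(h2_A / vA) else 0
  lamD <- if (h2_D > 0 && vD > 0) sqrt(h2_D / vD) else 0
  e <- rnorm(nrow(X), 0, sqrt(1 - h2_A - h2_D))
  y <- lamA * gA + lamD * gD + e
  names(y) <- rownames(X)
  vt <- var(y)
  list(
    y = y,
    effects = data.frame(
      marker = seq_len(m), a = lamA * a, d = lamD * d, causal = causal
    ),
    h2_A = var(lamA * gA) / vt, h2_D = var(lamD * gD) / vt
  )
}

#' Genotypes for an equilibrium or founder-derived panel
#'
#' With `founders = NULL`, an unstructured Hardy-Weinberg panel with
#' independent sites. With `founders = K`, each sample is a mosaic of two of
#' `K` founder haplotypes with a small number of crossovers, giving the
#' linkage disequilibrium and relatedness structure of a breeding panel
#' descended from a limited founder pool -- the regime in which genomic
#' relationship matrices are informative about variance components at panel
#' size.
#'
#' @param n samples.
#' @param m number of markers.
#' @param maf range of (founder-pool) allele frequencies.
#' @param founders number of founder haplotypes, or `NULL` for an
#'   unstructured panel.
#' @param crossovers expected crossovers per mosaic haplotype.
#' @param seed integer seed.
#' @return dosage matrix (n x m) with attribute `p` (allele frequencies).
#' @export
simulateGenotypes <- function(n, m, maf = c(0.05, 0.5), founders = NULL,
                              crossovers = 3, seed = 1L) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  if (is.null(founders)) {
    X <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  } else {
    H <- matrix(rbinom(founders * m, 1L, rep(p, each = founders)),
      founders, m
    )
    gamete <- function() {
      n_sw <- rpois(1, crossovers)
      cuts <- sort(sample.int(m - 1L, min(n_sw, m - 1L)))
      bounds <- c(0L, cuts, m)
      idx <- integer(m)
      for (b in seq_len(length(bounds) - 1L)) {
        idx[(bounds[b] + 1L):bounds[b + 1L]] <- sample.int(founders, 1L)
      }
      H[cbind(idx, seq_len(m))]
    }
    X <- t(vapply(seq_len(n), function(i) gamete() + gamete(), integer(m)))
  }
  rownames(X) <- sprintf("S%04d", seq_len(n))
  attr(X, "p") <- p
  X
}

#' DEG labels with depleted deleterious density
#'
#' Labels a fraction of genes as differentially expressed and relocates, with
#' probability `promoter_depletion`, each deleterious site lying in a DEG
#' promoter/body to a position outside all DEG regions. Nondeleterious site
#' placement is untouched, so the DEG/non-DEG contrast of nondeleterious
#' counts stays null.
#'
#' @param panel a severity-annotated [GenoPanel-class].
#' @param genes gene `GRanges` ([simulateGenes()]).
#' @param frac_deg fraction of genes labeled DEG.
#' @param promoter_depletion relocation probability in `[0, 1]`.
#' @param chrom_length chromosome length (defaults to the panel seqlengths).
#' @param seed integer seed.
#' @return list with `panel` (sites re-positioned, rows re-sorted) and
#'   `labels` (data.frame `gene_id`, `is_deg`).
#' @export
simulateDegLabels <- function(panel, genes, frac_deg = 0.3,
                              promoter_depletion = 0.5, chrom_length = NULL,
                              seed = 1L) {
  if (promoter_depletion < 0 || promoter_depletion > 1) {
    stop("promoter_depletion must lie in [0, 1]")
  }
  set.seed(seed)
  if (is.null(chrom_length)) {
    chrom_length <- GenomeInfoDb::seqlengths(SummarizedExperiment::rowRanges(panel))[1]
  }
  sizes <- setNames(
    rep(chrom_length, length(GenomeInfoDb::seqlevels(genes))),
    GenomeInfoDb::seqlevels(genes)
  )
  is_deg <- runif(length(genes)) < frac_deg
  labels <- data.frame(gene_id = genes$gene_id, is_deg = is_deg)
  regions <- buildGeneRegions(genes, sizes)
  deg_region <- GenomicRanges::reduce(regions$combined[is_deg])

  rr <- SummarizedExperiment::rowRanges(panel)
  sv <- SummarizedExperiment::rowData(panel)$severity
  if (is.null(sv)) stop("panel must be severity-annotated (annotateSeverity)")
  in_deg <- GenomicRanges::countOverlaps(rr, deg_region) > 0
  move <- which(in_deg & !is.na(sv) & sv != "NONDEL" &
    runif(length(rr)) < promoter_depletion)
  if (length(move)) {
    taken <- GenomicRanges::start(rr)
    for (i in move) {
      repeat {
        cand <- sample.int(chrom_length - 1L, 1L)
        g <- GenomicRanges::GRanges(
          GenomeInfoDb::seqnames(rr)[i],
          IRanges::IRanges(cand, width = 1L)
        )
        if (GenomicRanges::countOverlaps(g, deg_region) == 0 && !(cand %in% taken)) {
          GenomicRanges::ranges(rr)[i] <- IRanges::IRanges(cand, width = 1L)
          taken[i] <- cand
          break
        }
      }
    }
  }
  out <- panel
  SummarizedExperiment::rowRanges(out) <- rr
  out <- out[order(
    as.character(GenomeInfoDb::seqnames(rr)),
    GenomicRanges::start(rr)
  ), ]
  list(panel = out, labels = labels)
}
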