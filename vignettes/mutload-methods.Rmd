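---
title: "Models and methods behind mutload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mutload quantifies the burden of deleterious mutations in crop breeding
panels, how hybrids mask that burden, and how deleterious variants shape
quantitative traits. This vignette explains the models the package
implements, the conventions and defaults it adopts where the underlying
methods leave choices open, and what its synthetic-data generator does and
does not emulate.

## Severity classes and polarization

Sites are stratified by evolutionary constraint (GERP rejected-substitution
score) into four classes: nondeleterious (GERP ≤ 0), slightly deleterious
(0 < GERP ≤ 2), moderately deleterious (2 < GERP ≤ 4) and strongly
deleterious (GERP > 4). The literature phrasing leaves the boundary points
ambiguous; `classifyGerp()` uses half-open-above intervals so that 0, 2 and 4
fall into the lower class. This is a documented convention, not an inference.
A parallel protein-level annotation calls a site deleterious when it is
nonsynonymous with a SIFT score strictly below 0.05.

Derived alleles are established against a single outgroup: if the recorded
outgroup allele equals REF, the derived allele is ALT; if it equals ALT,
dosages are flipped; if it matches neither (or is missing) the site is
excluded rather than folded, because all downstream spectra are unfolded.
Exclusion rates are reported so users can monitor outgroup quality.

Coordinates live in `GRanges` (1-based, closed), the standard container in
this ecosystem; BED (0-based half-open) and GFF3 (1-based closed) files are
converted on import/export by rtracklayer, so the two encodings of the same
interval compare equal and round-trips are exact.

## Load accounting

Per-genome load is counted in two modes: *additive* (the dosage sum, so a
homozygous site contributes two units and a heterozygous site one) and
*recessive* (one unit per homozygous-derived locus, on the view that a
partially recessive allele expresses its damage mainly when homozygous).
Counting two units per homozygous locus is available via `hom_units = 2`;
the default of one unit is what makes the identity

> additive − 2 × recessive = number of heterozygous loci

hold exactly, which the test suite asserts against brute-force iteration.
Missing genotypes are excluded per sample and reported through `n_called`
and a per-called-site rate, so call-rate differences between samples cannot
masquerade as load differences. Group contrasts use the two-sided
Mann–Whitney test with percent change computed on group means (the
mean/median basis of published percent differences is usually unstated;
means pair naturally with the rank test reported alongside). Fixed load
follows the downsampling protocol: eras are subsampled to a common size (30
for the Chinese eras, 74 for the US eras) before counting sites at derived
frequency 1.

## Site frequency spectra

`projectSFS()` computes the expected projected spectrum: a site with `k`
derived among `m` called haplotypes contributes the full hypergeometric
distribution `P(j | k, m, n)` to the projected bins, rather than one random
subsample. This is the deterministic expectation of the usual downsampling,
preserves total site mass to numerical precision, and composes: projecting
`m → n1 → n2` equals projecting `m → n2`. Sites with fewer called haplotypes
than the projection size are dropped (and counted), not rescaled, to avoid
bin distortion. The joint SFS between two groups accumulates, per site, the
outer product of the two projection distributions at the common size
`2·min(|A|, |B|)`.

The asymmetry of a joint spectrum is summarized as
`sum_{i<j} |M_ij − M_ji| / sum_{i≠j} M_ij` after zeroing the monomorphic
corners: 0 for a symmetric matrix, 1 when all off-diagonal mass lies on one
side. Two properties of this index matter in practice. First, it measures
*net* reflection asymmetry, so balanced private variation on both sides
partially cancels; what keeps the between-group index high in realistic
panels is that breeding pools do not carry equal private burdens. Second,
finite samples inflate it, so comparisons should use a common projection
size (the package's study-scale analyses use 16) and a within-group null
built from era-balanced split halves — splitting a group by era would
measure real temporal drift, not sampling symmetry.

## Hybrids and complementation

Hybrid genotypes are deduced from the pedigree: two homozygous parents
determine the offspring genotype; residual parental heterozygosity or
missingness yields a missing call by default (inbred lines are near-fully
homozygous, and a deterministic rule keeps the inference reproducible); a
seeded gamete-sampling mode is available. Complementation is measured per
hybrid and severity class as the fraction of derived-allele-carrying sites
that are heterozygous; the denominator of all carrying sites is the default,
with all called segregating sites as an option. Fractions are reported
overall and within derived-allele-frequency deciles, with frequencies taken
from the pooled inbred panel. Genome-wide coupling between deleterious
density and hybrid heterozygosity uses 1-Mb non-overlapping windows with
both quantities normalized by the per-window SNP totals. Zero-variance
paired contrasts report an infinite t with p = 0 and a `degenerate` flag
rather than NaN.

## GBLUP, SNP effects, and null SNP sets

Variance components come from average-information REML with an EM fallback
whenever an AI step leaves the parameter space or decreases the restricted
likelihood; components are floored just above zero and convergence is a
log-likelihood change below 1e-6 (at most 200 iterations). The additive GRM
uses dosages centered at `2p` scaled by `Σ2p(1−p)`; the dominance GRM uses
heterozygosity indicators centered at `2p(1−p)` scaled by `Σ(2p(1−p))²` —
the standard VanRaden/Su parameterization of this model family. Per-SNP effects are recovered by the
BLUP backsolution `a = (σ²_A/c_A) W'Py`, `d = (σ²_D/c_D) H'Py`, with
explained variance `2pq·a² + (2pq)²·d²`. The conventional filter chain is applied: nonzero additive effect (operationalized as `|a| > 1e-12`,
because backsolved effects are never exactly zero in floating point),
explained variance strictly above the genome-wide mean, and degree of
dominance `|k = d/a| < 2`.

Frequency-matched null sets reproduce the target's minor-allele-frequency
histogram exactly in ten equal bins on (0, 0.5] ("bins of 10" being
ambiguous between ten bins and 10% bins, ten equal bins were chosen and are
configurable), sampling without replacement within a set, deterministically
per seed. LD pruning follows PLINK's `indep-pairwise` greedy procedure with a 50-SNP
window and 5-SNP step by default (the conventional values; analyses in this
domain typically report only the r² threshold, 0.1 here).

## BayesS-style coupling of effect size and allele frequency

`fitBayesS()` samples the spike-and-slab model
`β_j ~ π₁·N(0, σ²_β·(2p_jq_j)^S) + (1−π₁)·δ₀` with an intercept and the
leading principal components (three by default) as fixed covariates. Three
implementation decisions matter:

* the `log(2pq)` values are centered before entering the slab, so `S`
  controls only the tilt of effect variance across allele frequencies while
  the overall scale belongs to `σ²_β` alone — without this the two
  parameters share a posterior ridge that a random-walk update traverses
  poorly;
* `S` is updated by Metropolis steps against the *data* marginal of the
  currently included effects (a Woodbury computation on the included block),
  after which those effects are redrawn jointly from their exact
  multivariate-normal conditional; the cheaper update against the sampled
  effects alone is used between these sweeps;
* the mixture weight carries a sparsity-favoring Beta(1, 49) prior, which
  keeps the `S` update informed mainly by effects with genuine data support
  at panel-scale sample sizes.

Even so, users should know the small-panel behavior of this model class: at
a few hundred samples, which SNPs rise above the detection boundary is
itself frequency-dependent, and the posterior for `S` inherits both the
sampling noise of the realized genetic architecture (a few dozen causal
loci pin down the realized frequency–effect slope only to ±0.2–0.4) and a
detection-boundary tilt. Posterior means for a single trait at such sizes
are indicative, not sharp; credible intervals are honest and wide. The
full-scale chain of the published protocol (410,000 iterations, 10,000
burn-in) is available by argument; desk-scale analyses default to
20,000/2,000 with thinning.

## Inbreeding and runs of homozygosity

The inbreeding coefficient is the method-of-moments
`F = (O_hom − E_hom)/(L − E_hom)` with the small-sample-corrected expected
homozygosity `1 − 2p(1−p)·2n/(2n−1)` summed over each sample's called
polymorphic sites — the VCFtools `--het` convention. ROH detection
reproduces the PLINK-style scan: SNPs thinned to one per 2-kb bin, 20-SNP
windows sliding by one, at most 1 heterozygous and 2 missing calls per
window, a SNP in ROH when at least 5% of covering windows pass (the scanning
tool's default, exposed as `hit_fraction`), maximal runs emitted as segments
and kept at ≥ 300 kb. The implementation is verified against explicit window
enumeration across the parameter grid.

## The synthetic-data generator

`simulateILs()` runs a forward Wright–Fisher simulation with partial
selfing on one recombining chromosome (800 sites over 10 Mb, 2 Morgans, by
default). Five era groups with the study's sample sizes (30, 74, 95, 89,
53) sit on one chronological timeline — 1965, 1980, 1990, 2003, 2010 — with
per-heterotic-group effective sizes shrinking 500 → 50 and selfing rates
rising 0.5 → 0.95, so later eras are more drifted and more autozygous.
"Per group" is the natural reading here because each of the four heterotic
pools is a breeding population in its own right, and it keeps every era's
population large enough to draw the study-sized samples. Selection is
multiplicative with genotype fitnesses 1, 1−hs, 1−s and h = 0.25
(partial recessivity is what lets complementation act), and per-class
coefficients s = 0, 0.001, 0.02, 0.1 from nondeleterious to strong.

Two initial-state choices encode history that predates the simulated
timeline:

* deleterious variants start at mutation–selection-balance frequencies
  (U(0.01, 0.15)) rather than the neutral standing spectrum (U(0.05, 0.5));
* 70% of deleterious sites are *private to one heterotic group* at the
  start (home-group frequency U(0.1, 0.9), absent elsewhere), with
  home-group shares weighted 10/20/30/40% across SS/NSS/IDT/HZS.

The pools' divergence is decades older than the breeding eras being
simulated, so the initial state must already carry group-private deleterious
variation; drift over the ~85 simulated generations alone cannot create it.
Privacy is what makes between-group hybrids complement slightly deleterious
alleles while within-group crosses do not, and the unequal burden across
pools (the most intensively selected pool carrying the least) is what makes
the joint SFS between two pools visibly asymmetric — both patterns the
generator is meant to reproduce qualitatively.

`simulateGenotypes()` provides panels for variance-component and sampler
calibration: either an unstructured Hardy–Weinberg panel with independent
sites, or a founder-mosaic panel in which each sample combines two of K
founder haplotypes with a few crossovers. The mosaic mode reflects how
elite panels descend from a limited founder pool; the relatedness it creates
is precisely the information variance-component REML needs, and at
n = 300 × m = 2000 it is the difference between an estimable model (median
absolute error below 0.1 on both variance fractions) and one whose
sampling error alone exceeds that. The trait generator builds
`y = Σa_jx_j + Σd_j1[x_j = 1] + e` with `a_j ~ N(0, (2pq)^S)`, optional
inflation of deleterious `|a|`, `d_j = k_ja_j` with `k_j ~ U(0, 1)`, and
noise scaled to hit the target variance fractions exactly in sample.
Calibration analyses of the frequency–effect coupling use an oligogenic,
highly heritable trait (2% of markers causal, h²_A = 0.85, allele
frequencies down to 0.01): with 40 well-detected causal loci the realized
coupling is tight enough around its target to make sign recovery a
meaningful test, whereas a diffuse architecture leaves the realized slope
itself undetermined.

The generator does **not** emulate: new mutation during the timeline,
multiple chromosomes or realistic maize recombination maps, linked-selection
interference, migration between pools after the split, genotyping error, or
reference bias. Passing recovery tests on these simulations therefore shows
that the estimators measure what they claim on data with the assumed
structure — not that real resequencing panels satisfy those assumptions.

Problem sizes used in the packaged analyses (era simulations of 800 sites
with ~85 generations across 4 × 5 populations; calibration panels of 300 ×
2,000) were chosen so a complete study runs in minutes on a laptop while
every qualitative contrast of interest remains comfortably detectable at 20
replicates.

## Interval analyses

Gene regions combine the body with a strand-aware 2-kb upstream promoter
clipped at chromosome boundaries; a site on a boundary belongs to the
region under closed-interval membership, and a site falling in the regions
of several genes counts once per gene. Differential-expression contrasts
test per-gene deleterious counts between DEG and non-DEG sets with rank-sum
tests, running the same contrast on nondeleterious counts as the negative
control for overall-diversity differences. QTL enrichment uses the
one-proportion Z test with the nondeleterious in-QTL fraction as the null
proportion, plus a Pearson chi-square (no continuity correction by default,
matching the large-count regime; a flag enables it) on deleterious versus
synonymous-nondeleterious sites in and out of QTL. Candidate-locus
contrasts compare trait and expression between the two homozygote classes,
excluding heterozygotes, with at least two lines required per class.

## Known limitations

* The BayesS posterior mean for `S` at panel-scale n is noisy and can be
  tilted by the frequency-dependent detection boundary (discussed above);
  treat single-trait results as directional evidence only.
* The recessive-mode unit (loci, not alleles) and the percent-change basis
  (means) are conventions; both are configurable where they matter.
* The asymmetry index is a package-defined summary of a visual claim; no
  published numeric value exists for it.
* Hybrid inference discards sites with residually heterozygous parents by
  default, slightly under-counting heterozygosity if parents are not fully
  inbred.
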