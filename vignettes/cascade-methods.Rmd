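---
title: "Methods: the filtration cascade, cohort statistics and SKAT-O"
author: "somaticCascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the filtration cascade, cohort statistics and SKAT-O}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticCascade)
```

# Scope and model

`somaticCascade` analyzes tumor-only targeted cancer-panel cohorts — the
setting of deep amplicon sequencing of a few hundred cancer genes from FFPE
tumor tissue without matched normals. Because there is no matched normal,
somatic status cannot be established directly; instead variants are routed
through a classification cascade built on public databases and simple
heuristics:

1. **Quality gate.** A call survives if its coverage is *strictly greater*
   than 300x and its site QUAL is *strictly greater* than 50. We read the
   thresholds as strict because that is the literal convention ("more than"),
   and both are configurable in `FilterConfig()` so the boundary can be
   moved either way. QUAL is taken as the read-quality field; targeted
   pipelines differ in what they emit, and the site-level QUAL is the one
   field always present.
2. **Common-variant exclusion.** Variants previously reported in Ensembl are
   excluded as presumed germline polymorphisms *unless* COSMIC marks them
   confirmed-somatic or pathogenic (FATHMM-based label). An optional
   population-allele-frequency override (> 1%) is exposed but off by
   default.
3. **Novelty.** A variant absent from COSMIC is *novel vs COSMIC*; if it is
   also absent from ICGC it is *novel against both* databases.
4. **Pathogenic routing and tissue specificity.** COSMIC-pathogenic variants
   with a prior report in the target tissue (default `large_intestine`) are
   *tissue-specific pathogenic*; pathogenic variants never reported there
   are *first-time-in-tissue* — the set a discovery analysis focuses on.
5. **Germline inference from VAF.** In tumor-only data a variant allele
   fraction near 50% or 100% suggests germline origin. A variant is
   *germline-suspect* when at least one carrier's VAF lies in the closed
   bands [49, 51] or [99, 100] (percent scale — we store VAF in percent
   because the bands are conventionally quoted that way). The suspicion is
   *MAF-supported* when the cohort minor allele frequency exceeds 1%.
   Since tumor-only calls carry no genotypes, the cohort MAF counts each
   carrier as one minor allele over `2 * nSamples` chromosomes. This is a
   stated convention (what a PLINK-style run on presence/absence calls
   sees), not a claim about true genotypes.
6. **Damaging inclusion.** Variants deleterious on SIFT and/or damaging on
   PolyPhen-2 are flagged for downstream analysis; "damaging" includes both
   probably- and possibly-damaging PolyPhen levels.

Flags are cohort-level: one row per variant key `(chrom, pos, ref, alt)`
after multi-allelic splitting, with carrier VAFs aggregated across samples.
Coordinates are 1-based VCF conventions and indels are taken as given (no
re-normalization). When a variant maps to several transcripts the
annotation table must pre-resolve one gene per variant (canonical-transcript
convention); the pipeline does not re-pick.

## Open points resolved as design choices

* The published cascade does not state whether its pathogenic set is nested
  in its confirmed-somatic set. We default to nesting (the per-gene
  composition of the most-mutated gene supports it: all of its pathogenic
  variants are among its somatic ones), but `cascadeCounts()` reports both
  sets *and* their intersection, so no information is lost if the overlap is
  partial.
* Whether the working total of variants is pre- or post-quality-gate is
  ambiguous; `cascadeCounts(postQualityOnly = FALSE)` reports the pre-gate
  tally alongside the default post-gate one.
* Consequence and SIFT/PolyPhen category tallies are reported on the
  confirmed-somatic subset, which is the set the published category figures
  classify.

# The synthetic cohort generator

The generator emulates the *annotated* outputs of a tumor-only panel
pipeline, not reads or alignments. Its defaults are the study conditions:
90 patients, a 409-gene panel (synthetic symbols `G001..G409`; the real
gene list can be supplied), and a cascade composition of 4256 variants with
483 absent from COSMIC (17 of them in ICGC), 561 confirmed somatic, 299
pathogenic with 125 previously reported in the large intestine, and 69
germline-band variants of which 45 are MAF-supported.

Two properties matter for testing:

* **Count-exact realization.** Cascade category sizes are realized by
  partitioning a shuffled index vector, not by Bernoulli draws, so
  `cascadeCounts()` on a generated cohort returns the target composition
  *exactly* and cascade regression tests are deterministic.
* **Full determinism.** The same `CohortConfig` (including seed) produces
  byte-identical tables.

Choices the data do not pin down, made once:

* Somatic VAFs are drawn from Beta(2, 3) scaled onto (5, 95)% — a plausible
  right-of-center spread for FFPE tumor-only panels with varying purity —
  and rejection-sampled out of the germline bands (with a 0.2-point margin
  absorbing depth rounding) so band membership stays count-exact. The
  published study does not state its VAF distribution; this is a stand-in,
  not an estimate of the study data.
* Germline-band variants are drawn preferentially from the COSMIC-absent
  set, mirroring the germline screen being applied to novel variants.
  MAF-supported ones receive `floor(0.02 * n) + 1` or more carriers
  (pushing cohort MAF above 1%); the rest exactly `floor(0.02 * n)` (one
  carrier at the default cohort size).
* Clinicopathological features are drawn from the published marginal
  tables (58/37 male/female; stages 17/32/37/8; T 2/18/61/13; N 55/33/6;
  M 90/4; site 47/30/13; age mean 62, SD 14) with *independent* joint
  structure — only marginals are published.
* Carrier multiplicity is `1 + Poisson`, scaled so the expected number of
  calls matches `nPatients * variantsPerPatient` (default 70 calls per
  patient).

What passing tests on synthetic cohorts do **not** show: robustness to
annotation errors, multi-gene transcripts, indel normalization differences,
panel coverage dropout, or correlated clinicopathological features — none
of which the generator emulates.

# Association statistics

These are authored from first principles (the package's contribution), with
base-R distribution functions underneath and independent oracles in tests.

* **Fisher's exact test** (two-sided) uses the probability-ordering
  convention: the p-value sums hypergeometric probabilities of all tables
  with the observed margins whose probability does not exceed the observed
  table's (relative tolerance 1e-7 for floating-point ties). This matches
  the widely used implementation family. The reported odds ratio is the
  sample cross-product ratio `ad/bc`, not the conditional MLE.
* **Chi-square** (2x2) is uncorrected — the published site associations
  quote plain chi-square and no continuity correction is stated.
* **Co-occurrence correlation** is Pearson on 0/1 incidence vectors, which
  is algebraically the phi coefficient of the 2x2 cross-table; two-sided
  p-values come from `t = r sqrt((n-2)/(1-r^2))` on `n - 2` df. Star
  annotation uses the conventional 0.05/0.01/0.001 levels, with no FDR
  layer on the correlation matrix (none was applied in the source
  analysis). Outputs carry both `r` and `r^2`-recoverable values, since the
  field mixes the two notations.
* **Exact HWE** enumerates heterozygote counts conditional on the allele
  counts, summing probabilities at most the observed configuration's.
* **Bonferroni**: `alpha / m`; at `alpha = 0.05` over 409 genes this is
  1.22e-4, i.e. 0.0001 at one significant figure.

# The SKAT-O family

With genotype matrix `G` (n individuals x m variants), Beta(1, 25) weights
`W = diag(w(MAF))` (rare variants upweighted; `a = b = 1` recovers the
unweighted test), null residuals `r` and null variance `V`, the family is

```
Q_rho = (1 - rho) Q_SKAT + rho Q_burden = r' (GW) R_rho (GW)' r,
R_rho = (1 - rho) I + rho 11'
```

`rho = 0` is SKAT, `rho = 1` the weighted burden test; the default grid is
the standard 8 points (0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1). Null
models are intercept-only by default (logistic IRLS for binary traits,
tolerance 1e-10; OLS for quantitative), matching the published usage;
covariates can be supplied.

Per-rho p-values come from the chi-square-mixture tail with eigenvalues of
`S_rho B S_rho`, where `B = (GW)' P (GW)` is the null score covariance and
`S_rho` the symmetric square root of `R_rho`. The mixture tail is computed
by Imhof's characteristic-function inversion (a Davies-type numerical
inversion, target absolute accuracy 1e-9) using vectorized composite
Simpson quadrature with oscillation-aware truncation and Richardson
extrapolation; the modified Liu moment-matching approximation is the
logged fallback when inversion fails, exceeds its cost bound, or cannot
resolve a very small p. The combined p-value for the minimum over the grid
uses the standard one-dimensional integration of the optimal-test
construction, with two numerical safeguards: the outer quadrature is
restricted to the support where the integrand is nonzero (otherwise the
adaptive rule can miss the burden-constrained spike near the origin and
return exactly 1), and the result is clamped to
`[min per-rho p, grid-size x min per-rho p]`, the bounds the min-p
statistic implies.

Tumor-only carrier encoding (each carrier heterozygous) feeds the screen;
no variants are excluded — common ones are simply down-weighted — so the
per-gene marker counts `N.Marker.All` and `N.Marker.Test` coincide.
Small-sample binary adjustments from specific published implementations
are not reverse-engineered; instead an optional residual-permutation
p-value (`usePermutation = TRUE`, 2000 permutations by default, using the
Liu transform for per-permutation min-p ranking) is available as the
small-sample safeguard, and `methodLabel` records which path produced each
p-value.

Calibration, verified by the test suite on each run: over 500 null
replicates (n = 200, 10 variants, binary trait) the empirical type-I error
at alpha = 0.05 lies within [0.03, 0.07] and the null p-values are
approximately uniform (Kolmogorov-Smirnov).

# Problem sizes and numerical choices

The test suite and acceptance script use these sizes, chosen to make the
Monte-Carlo checks statistically meaningful while keeping a full run in the
minutes range on one core: 500 null replicates for SKAT-O calibration
(n = 200, 10 variants); 200 replicates for Fisher power against an
injected odds-ratio-8 association in a 300-patient cohort; 1e5-draw
Monte-Carlo references for quadratic-form tails (3-SE agreement); full
enumeration oracles for Fisher (tables up to n = 40) and HWE. Degenerate
inputs are defined, not errors, wherever filtering semantics allow: the
quality gate never throws on content, an all-zero genotype matrix yields
p = 1 with a warning, empty margins yield Fisher p = 1 with a missing odds
ratio, and constant genes are excluded from the correlation matrix with a
notice.

# Known limitations

* The co-mutation GraphML export is a structural stand-in for proprietary
  knowledge-base network analysis; it encodes only the correlation
  structure and makes no pathway or biomarker claims.
* Cohort-scale headline frequencies of the motivating study (per-gene
  sample percentages, specific correlation coefficients) depend on
  unreleased per-variant data and specific database versions, and are not
  reproducible from synthetic cohorts; the package reproduces the
  cascade arithmetic, printed descriptives and the statistical machinery,
  and verifies the latter by property-based testing.
* The VCF reader covers the minimal single-sample, DP/AD/AF subset the
  pipeline emits; phasing, structural variants and gVCF blocks are out of
  scope.
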