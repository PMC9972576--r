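---
title: "Assessing long-term stability of array DNA methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing long-term stability of array DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylstab)
```

## The problem

Epigenome-wide association studies in chronic disease increasingly propose
blood DNA methylation as a biomarker. A biomarker is only useful if the
CpGs carrying it are *temporally stable* within a person: a locus whose
methylation drifts with age, cell composition or environment cannot
separate disease signal from elapsed time. Given paired beadchip-array
samples from the same subjects at two time points (T1, T2) several years
apart, `methylstab` answers, per CpG:

1. How reliable is the measurement across time (intra-class correlation)?
2. Is an apparently ultra-stable signal actually a genotype artifact
   (a probe sitting on a germline variant)?
3. Which positions change systematically with time, and are those changes
   enriched for known age-associated ("epigenetic clock") CpGs?
4. How much of the change is attributable to shifting leukocyte
   composition?

## Reliability model: ICC(C,1)

For probe $p$, let $y_{ij}$ be the beta value (methylation fraction, in
$[0,1]$) of subject $i = 1 \dots n$ at occasion $j \in \{1, 2\}$. The
two-way mixed, single-measures, *consistency* intra-class correlation is
estimated from the two-way ANOVA decomposition

$$\mathrm{ICC}(C,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E},$$

with $MS_R$ the between-subject and $MS_E$ the residual mean square, and
$k = 2$ occasions. "Consistency" means a systematic occasion shift (e.g. a
cohort-wide drift between T1 and T2) does not count against a probe; this
is the right estimand for ranking probes by within-subject
reproducibility, and `icc_consistency()` is shift-invariant by
construction (adding a constant to one occasion leaves the estimate
unchanged, rescaling one occasion does not — both are asserted in the test
suite).

The null ICC $\le 0$ is tested one-sided with $F = MS_R / MS_E$ on
$(n-1,\,(n-1)(k-1))$ df, and 95% confidence bounds come from the standard
F-bound construction. Two conventions deserve note:

* **Negative estimates are reported as-is** and classified *poor*.
  Truncating at zero would bias any census of stability classes.
* **One-sided F p-value.** The reliability-software convention; the null
  is "no more between-subject than within-subject variance".

Estimates are binned with the Koo–Li reliability thresholds: poor
(ICC < 0.5), moderate (0.5–0.74), good (0.75–0.89), excellent
($\ge$ 0.9). All boundaries are half-open exactly as stated; the bins are
frozen in `classify_icc()`.

The screen runs on **raw beta values, complete pairs per probe, with no
covariate adjustment**. This is deliberate: any normalization or
adjustment that removes between-sample variance inflates apparent
stability, and the point of the screen is to find signals that are stable
*despite* everything that happened between the samplings. Probes with
fewer than 80% of the maximal pair count are flagged (`low_coverage`) and
left out of the multiplicity adjustment; the threshold is an argument.

A *stably methylated position* (SMP) requires ICC $\ge 0.75$ **and** a
Benjamini–Hochberg-significant ICC test; a *hyper-stable* position (HSMP)
additionally requires ICC $\ge 0.9$ and no genetic-variant evidence of any
kind. Both cutoffs and the significance level are arguments of
`call_stability()`.

## Genotype artifacts

Bisulfite-based arrays cannot distinguish an unmethylated cytosine from a
C→T variant, so probes over polymorphic sites show near-perfect
"stability" that has nothing to do with epigenetics. Three evidence
sources are combined, with precedence
`qc_gv > annotated_gv > predicted_gv > methylation`:

* **QC-GV probes** — the array's built-in genotyping control probes,
  supplied as an annotation flag (`is_qc_gv`) rather than a hard-coded
  list, since manifests and import pipelines disagree on the exact count.
* **Annotated GV probes** — probes whose target CpG carries a catalogued
  dbSNP variant (`annotated_gv`).
* **Predicted GV probes** — probes flagged by gap hunting
  (`hunt_gaps()`): sort a probe's beta values, cut at successive
  differences larger than `threshold = 0.05`, and call a gap signal when
  at least two groups remain. A signal whose minor groups together hold
  fewer than `out_cutoff = 0.01` of samples is *outlier-driven* and, by
  default, not treated as a genotype signal. Both defaults follow the
  published gap-hunting tool's documented defaults. Both timepoints are
  pooled for the scan (genotypes are time-invariant, so pooling doubles
  cluster occupancy without changing the number of clusters); a
  single-timepoint scan is available via the `samples` argument.

HSMPs are, by definition, disjoint from all three GV classes; the pipeline
asserts this invariant.

## Paired differential methylation

Time-associated change is modelled per probe by ordinary least squares on
beta values against time point (T2 = 1), sex, smoking, disease, and the
estimated cell-type fractions, exactly one fraction (neutrophils by
default) dropped against the intercept. Residual variances are then
shrunk toward a common prior by the empirical-Bayes scheme for
scaled-inverse-chi-square priors: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the prior df $d_0$ solves
$\psi'(d_0/2) = \mathrm{var}(e) - \overline{\psi'(d_g/2)}$ (infinite when
the observed variances show no excess dispersion, in which case the
posterior is the pooled variance), and
$s^2_{\text{post}} = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ feeds the
moderated t on $d_0 + d_g$ df (capped at the pooled residual df). The
implementation is validated two ways: parameter recovery against the
generating $(d_0, s_0^2)$, and numerical agreement with an independent
reference implementation of the same estimator in the test suite.

Two modelling decisions were genuinely open:

* **Beta versus M-values.** The model is fitted on beta values, matching
  the convention of regressing methylation ratios directly; beta-scale
  coefficients are directly interpretable as methylation differences. The
  heteroscedasticity of betas near 0/1 is partly absorbed by the variance
  moderation. An M-value analysis can be run by transforming the matrix
  before `fit_probes()`; it changes variance properties and effect-size
  units, which is why it is not the default.
* **No subject random effect.** With every subject contributing exactly
  one sample per time point, the design is balanced and the time
  coefficient is estimable by fixed effects alone; the quoted model for
  this analysis type includes only fixed covariates. A subject-blocked
  sensitivity analysis can be built by adding subject indicator columns
  via `build_design(extra = ...)` at the cost of df.

`call_dmps()` reports, besides the adjusted coefficient, the *unadjusted*
mean paired difference (`delta_beta`), which equals the paired mean
difference used by the ICC module on the same data — a deliberate
shared-statistic consistency, asserted in tests.

Epigenetic-clock CpG sets are tested competitively by a Wilcoxon rank-sum
of the set's moderated t-statistics against all other probes
(`set_rank_test()`), with directional alternatives (`"down"` for a
hypomethylation-with-time pattern).

## Cell deconvolution

Composition is estimated per sample by non-negative least squares of the
sample's beta values over the reference CpGs onto a reference panel of
cell-type-specific methylation (`deconvolve()`, Lawson–Hanson NNLS), with
post-hoc normalization of the weights to the simplex — the dominant
convention for this estimator family. Raw weights are retained, making the
estimate scale-consistent. The reference panel is a user input; selecting
reference CpGs is out of scope. Composition shifts between time points are
tested per cell type with a two-sided Mann–Whitney U test (the quoted
convention for this comparison), with a paired signed-rank alternative
behind `paired = TRUE` because the design is, in fact, paired.

## Gene-set enrichment with probe-count bias correction

Genes covered by many probes are more likely to contain at least one
significant probe. `test_gene_set()` therefore tests the set's
significant-gene count against a Wallenius noncentral hypergeometric null
whose odds are the ratio of mean probe counts (set versus non-set genes),
rather than the central hypergeometric of Fisher's test. This is a
single-scalar-odds simplification of the full per-gene-weight correction;
the exact multivariate version is a possible extension, but the scalar
form already restores type-I error under a probe-count-biased null (the
acceptance suite measures both the inflation of the uncorrected test and
the calibration of the corrected one). The pmf is evaluated by numerical
integration of its integral representation after the substitution
$t = s^d$, which turns the integrand into a smooth Beta-like kernel; at
odds 1 the implementation reduces to `phyper` to $10^{-6}$ (asserted).

## The synthetic cohort generator

No raw cohort data accompany this analysis type, so every stage is
validated against `simulate_cohort()`, which produces a paired EPIC-like
cohort with known truth. Defaults encode the study conditions: 46
subjects, two samples each, sampling interval uniform on 2–9 years
(median 7 in expectation matches the design's reported median), disease
mix ≈ 36:10 CD:UC, ~24% active smokers, ~50% female.

Probe classes and their generative models:

* **Variance-component probes** — latent
  $m_{ij} = \mu_p + b_i + \varepsilon_{ij}$ with
  $b_i \sim N(0, \sigma_r^2)$, $\varepsilon \sim N(0, \sigma_e^2)$ and
  $\sigma_r^2/(\sigma_r^2+\sigma_e^2)$ equal to the configured true ICC
  (levels 0.2/0.5/0.8/0.95 by default, total sd 0.05 on the beta scale),
  $\mu_p \sim U(0.15, 0.85)$, clipped to $[0.001, 0.999]$. The
  latent-Gaussian-with-clipping choice (rather than a logit-normal) keeps
  the true ICC exactly interpretable on the measurement scale; with these
  defaults the clipped fraction is well below 1% and is reported in the
  truth tables.
* **Genotype probes** — per-subject genotype drawn once from
  Hardy–Weinberg proportions at the configured MAF (default range
  0.2–0.5), cluster means 0.05/0.5/0.95, cluster sd 0.02, genotype
  constant across timepoints. A configurable number (default 59, the
  manifest rs-probe count; settable to other conventions) is flagged as
  QC-GV; half of the rest carry a dbSNP annotation, the other half are
  only discoverable by gap hunting — exercising all three GV evidence
  paths.
* **Age-drift probes** — add `drift_per_year` × interval at T2 (default
  −0.003 beta/yr, i.e. hypomethylation with time, the direction expected
  for clock CpGs in adults).
* **Cell-driven probes** — mixtures $\beta = \sum_c w_{ic} m_{pc}$ of a
  six-cell-type reference panel (B, CD4T, CD8T, NK, monocytes,
  neutrophils) with per-sample Dirichlet weights whose concentration
  (25) and mean reflect typical adult leukocyte fractions, plus
  measurement noise (sd 0.02). T2 weights are shifted by a configured
  vector (default +0.025 B, +0.025 CD4T, −0.05 neutrophils) to encode a
  modest composition change of the kind seen over multi-year follow-up.

What the generator does **not** emulate: batch/chip effects, detection
p-values, probe cross-reactivity, spatially correlated methylation,
non-Gaussian per-probe error, or clinical covariates that actually
influence methylation (CRP and leukocyte counts are drawn independently
of the beta values, with no T1→T2 shift, matching a cohort in which these
markers were stable). Passing tests therefore demonstrate the estimators'
correctness and calibration under the declared models — not robustness to
everything real arrays do.

## Numerical choices

* **Degenerate ICC inputs.** Zero residual mean square with
  between-subject signal (e.g. T2 an exact copy of T1) returns ICC 1,
  p 0, CI (1,1) with a `degenerate` flag; an all-identical matrix returns
  `NA`. The zero-residual test uses a relative tolerance
  ($SS_E \le 10^{-12} \cdot SS_{tot}/nk$) so floating-point residue in
  exact-duplicate data is classified correctly.
* **Trigamma inversion** for the prior df uses Newton iteration with the
  standard asymptotic guards at both extremes.
* **Ties in nearest-variant distance** go to the smaller coordinate;
  vicinity flags are strict (`distance < 1000`), and coordinates are
  1-based inclusive throughout (Illumina manifest convention); BED input
  is converted explicitly.
* **Zero differences in the paired signed-rank test** follow the standard
  discard convention; an all-zero difference vector is reported as p = 1.
* **BH with missing p-values** adjusts over the non-missing entries and
  propagates `NA`.

## Validation design and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`) and the
reporting script (`scripts/acceptance.R`) recompute, from scratch:
the closed-form ICC against a brute-force ANOVA oracle on $10^4$ random
matrices ($n \in [3, 100]$); per-level recovery of the four true-ICC
levels over 20 cohorts of 46 pairs × 20,000 probes; one-sided F
calibration on $10^4$ null probes; gap-hunting sensitivity/specificity on
2,000 trimodal + 2,000 unimodal probes at 92 samples; NNLS weight
recovery over 200 samples × 300 reference CpGs (noise sd 0.01);
empirical-Bayes prior recovery at $d_0 = 4$, $s_0^2 = 0.01$ over $10^4$
probes plus a Kolmogorov–Smirnov uniformity check of null moderated
p-values; BH false-discovery control on null cohorts; clock-set rank-test
power over 20 drift cohorts plus random-set calibration; Wallenius versus
Fisher type-I error under a probe-count-biased null (1,200 genes, 2,000
replicate sets); and same-seed determinism plus census-conservation
invariants of the full pipeline. These sizes were chosen so each property
is measured with useful precision while the whole suite stays readily
re-runnable on a laptop.

## Known limitations

* The ICC screen assumes approximately Gaussian within-probe errors; the
  F-test calibration is exact only under that assumption (the suite
  verifies it on Gaussian nulls).
* The scalar-odds Wallenius correction is an approximation to the
  per-gene-weight model; with extreme probe-count skew it can under- or
  over-correct.
* Two time points cannot distinguish monotone drift from state change;
  `drift_per_year` is identified only up to the interval distribution.
* With $k = 2$ and moderate $n$, single-probe ICC confidence intervals
  are wide; class-level summaries (the census) are the intended readout,
  not per-probe certainties.
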