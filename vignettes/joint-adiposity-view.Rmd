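---
title: "A joint view of adiposity GWAS signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A joint view of adiposity GWAS signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide association studies of related anthropometric traits are often
run on covariate-adjusted phenotypes: waist-to-hip ratio adjusted for body
mass index (WHRadjBMI) is the canonical example.  Adjusted-trait effects are
sometimes read as "fat distribution independent of overall adiposity", and
sometimes dismissed as potentially biased.  Both readings miss what the
adjusted effect actually is.  If `r` is the phenotype correlation between
BMI and WHR, the genetic effects of a variant on the three traits
(all on inverse-normal-residual SD scales) satisfy, to close approximation,

```
b_WHRadjBMI = b_WHR - r * b_BMI .
```

A null WHRadjBMI effect therefore means "the WHR effect is exactly what the
BMI effect predicts through the phenotype correlation" — the variant sits on
the *null line* `b_WHR = r * b_BMI` of the (b_BMI, b_WHR) effect plane.  A
non-null adjusted effect marks an *unexpected* change in fat distribution
given the BMI change.  This package implements the joint-view analysis built
on that identity:

1. **Selection and clumping** of genome-wide significant variants
   (P < 5e-8, strict) across the BMI, WHR, and WHRadjBMI scans, unioned
   with scan provenance and greedily clumped into independent signals
   (a candidate is tied to a lead if it lies within 500 kb to either side
   *or* has r² > 0.1 with it; the lead is the variant with the smallest
   p-value across scans).
2. **Effect algebra**: conversion between adjusted and unadjusted effects
   in both directions, standard-error propagation, z-score-to-beta
   conversion for lookup consortia, and fixed-effect inverse-variance (IVW)
   meta-analysis of sex strata.
3. **Classification** of each lead variant by its nominally significant
   (alpha = 0.05) effect directions on BMI and WHR: `BMI+WHR+` (both, same
   direction), `BMIonly+`, `WHRonly-`, `BMI+WHR-` (both, opposite), with
   class-specific allele alignment so that all four classes report
   hip-increasing alleles.
4. **Directional enrichment**: per class and lookup trait, binomial tests
   of the count of nominally significant trait-increasing (or -decreasing)
   effects against the null rate.
5. **Class-restricted Mendelian randomization**: the IVW slope of outcome
   effects on BMI effects using one class's variants as instruments, which
   is exactly the zero-intercept weighted regression line through the
   class's effect scatter (a genetic-risk-score meta-regression).

Everything runs against a seeded synthetic generator, so the whole pipeline
is testable without consortium downloads.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| genome-wide threshold | 5e-8 | strict inequality, per scan |
| nominal alpha | 0.05 | non-null effect call in classification and lookups |
| strict alpha | 0.05 / n_signals | sensitivity re-classification |
| clump window | 500,000 bp | to either side of the lead, 1-based positions |
| clump r² | 0.1 | absorb when above; both criteria must clear for independence |
| minimum N | 10,000 | per-record QC |
| r (combined / women / men) | 0.44 / 0.46 / 0.60 | BMI-WHR phenotype correlation |
| enrichment null rate | alpha/2 = 0.025 | per direction |
| enrichment Bonferroni | 0.05 / (classes × traits × 2) | e.g. 0.05/168 for 21 traits |
| MR Bonferroni | 0.05 / (3 eligible classes × outcomes) | e.g. 0.05/60 for 20 outcomes |

The enrichment null rate deserves a note: a two-sided nominal test at 0.05
splits into 0.025 per direction, and under the null each aligned variant is
trait-increasing-significant with probability 0.025.  This value uniquely
reproduces the published tails (e.g. 82 of 82 gives 0.025^82 ≈ 4.3e-132) and
is fixed, not tunable, in `run_enrichment()`.

## Standard-error propagation

`unadjusted_from_adjusted()` propagates `se² = se_adj² + r² se_BMI²`,
treating the two estimates' sampling errors as independent.  The covariance
between the adjusted-trait and covariate estimates is approximately zero by
construction of the adjustment, and under the package's own direct sampling
model the approximation is exact: the converted null z-statistic has unit
variance, which the calibration test verifies by a Kolmogorov–Smirnov check.
Computed SEs are always larger than directly estimated ones (the
`mean_se_ratio` around 1.09 in the worked example), so conversion trades a
third genome-wide scan for a small precision loss.  p-values are always
recomputed from `beta/se`; input p-values are discarded after conversion.

## The synthetic generator

`architecture_spec()` plants a four-class effect architecture:

- *concordant* variants lie **on the null line** (`b_WHR = r * b_BMI`,
  both positive): fat distribution changes exactly as expected given BMI,
  i.e. a structurally null WHRadjBMI effect;
- *bmi_only* variants have `(b_BMI, 0)` — note their true WHRadjBMI effect
  is `-r * b_BMI`, not zero;
- *whr_only* variants have `(0, -b_WHR)`;
- *discordant* variants have `(+b_BMI, -b_WHR)`.

Defaults mirror the scale of the real catalogue: class counts 82/25/28/24,
MAF uniform on (0.1, 0.5), per-allele effects 0.05 SD, phenotype
correlations 0.44 overall and 0.46/0.60 by sex, logistic disease with
intercept -2 (prevalence ~0.12 at the mean) and 0.5 log-odds per SD of BMI,
with an optional WHR path for protective-class experiments.  Two generation
routes exist and are tested against each other (two-sample KS on null
z-scores):

- `simulate_cohort()` draws genotypes binomial(2, MAF) and phenotypes as
  genetic score plus correlated noise, solved per sex so the within-sex
  phenotype correlation hits its target exactly (an unreachable target, given
  the planted genetic covariance, is a parameter error).  Phenotypes are
  inverse-normal transformed with the Blom offset `(rank - 3/8)/(n + 1/4)`
  (any fixed standard offset would do; this one is documented and frozen)
  within sex; WHRadjBMI residualizes WHR on BMI within sex before the
  transform, matching consortium practice of sex-specific residualization.
  The combined stratum pools the per-sex transformed values.
- `sumstats_direct()` draws effect estimates straight from the sampling
  model, `beta_hat ~ N(beta, se²)` with `se = 1/sqrt(2 f (1-f) N)` and
  BMI/WHR error correlation `r`.  The adjusted trait follows by the linear
  relation on the re-standardized residual scale,
  `b_adj = (b_WHR - r b_BMI)/sqrt(1-r²)` with `se_adj = se`, which matches
  the cohort route's moments (the residual has variance `1-r²` before its
  inverse-normal re-standardization).  Optional LD satellites with a chosen
  r² give the clumping stage realistic work.

What the generator deliberately omits: covariate confounding (age, principal
components), population structure, relatedness, long-range LD beyond the
planted blocks, and between-study heterogeneity of a real meta-analysis.
Passing tests therefore demonstrate the correctness of the statistical
machinery under the assumed sampling model, not robustness to the
data-quality pathologies of real consortium files.

## Design choices in genuinely open territory

- **Calibrated effect mode.** Experiments that need controlled per-variant
  power use `effect_mode = "calibrated"`, fixing the association z-score
  (equal variance explained per locus) instead of the per-allele beta.  The
  discovery-regime experiments use BMI z ≈ 7.8 — detection power near the
  genome-wide margin, which is where newly discovered loci live.  This
  matters for the scan-membership property: the separation of BMI-derived
  from WHRadjBMI-derived variants is a *power* phenomenon.  A `bmi_only`
  variant's true adjusted effect is `-r b_BMI`; at very large
  non-centrality the WHRadjBMI scan detects it and the scan separation
  collapses (as it must with growing sample sizes).  At the discovery
  margin the adjusted z is ~0.49 times the BMI z, far below the threshold,
  and WHRadjBMI-derived leads land in the WHR-decreasing classes.
- **Structural cap on the confusion diagonal.** For classes defined partly
  by a *null* trait (`BMIonly+`, `WHRonly-`), a truly null trait is
  nominally significant with probability alpha, so the attainable
  truth-to-label diagonal is capped at `(1 - 0.05) × power`, i.e. just
  under 95% no matter the sample size.  Recovery checks therefore test
  that the observed diagonal is not significantly below 95% (one-sided
  exact binomial at 0.001) rather than demanding a literal 95% that the
  data-generating process cannot exceed in expectation.
- **Strand-ambiguous variants** (A/T, C/G) are kept and flagged, not
  dropped: no palindromic rule is part of the published method, and the
  flag lets users filter downstream.
- **Clumping ties** (identical minimum p) break by chromosome, then
  position, then variant ID, making the greedy algorithm deterministic
  under input reordering.
- **Supra-expected effects** (WHR effect beyond `r b_BMI` by more than
  1.96 propagated SEs, same direction) are emitted as a metadata flag, not
  a class: the classification keeps the published four classes and the
  flag reproduces the handful of supra-expected variants as annotation.
- **Joint allele-score risk** is defined as the exponentiated sum of
  aligned per-allele log-odds over a class (log-additive independent
  effects).  The published headline relative risks are stated without a
  formula; this definition is recorded as an interpretation and the
  summary is additive over disjoint subsets by construction.
- **MR estimator.** First-order IVW weights (`1/se_outcome²`) only;
  exposure-side uncertainty is not propagated into the weights, matching
  the standard summary-statistic estimator, and Cochran's Q is emitted as
  a heterogeneity diagnostic.  With a binary outcome the per-variant
  marginal log-odds are mildly attenuated relative to the conditional
  causal parameter (non-collapsibility), and weak-instrument error in the
  exposure effects adds a small regression dilution; at the default
  operating point (50,000 individuals, 20 instruments of 0.05 SD/allele)
  the combined attenuation is a few percent of the planted effect and well
  inside two slope SEs.

## Problem sizes used in the shipped experiments

Conversion fidelity runs one 50,000-individual, 200-variant cohort (plus a
dimorphic twin); classification recovery pools 20 seeded replicates of the
159-variant architecture through selection, clumping and classification; MR
recovery runs 200 cohort replicates of 20 instruments at 50,000 individuals.
These sizes give Monte-Carlo error comfortably below every margin being
tested while keeping a full run on a laptop in minutes.

## Known limitations

- The p-vs-beta/se consistency filter works on the -log10 scale with a 10%
  relative tolerance (absolute floor 0.1 near p = 1); heavily rounded
  legacy files may need a looser map.
- LD handling is a pair table; there is no reference-panel computation, no
  conditional/joint secondary-signal analysis, and clumping absorbs only
  against the lead (no transitive chaining), per the published rule.
- The sex-difference test defaults to independent strata (rho = 0);
  consortia with overlapping samples should supply the estimate
  correlation.
- Real-data reproduction of the published catalogue requires the public
  GIANT downloads and an LD reference; the package reads those files as-is
  (`read_sumstats()` with the default column map) but does not fetch them.
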