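---
title: "Methods: voxel- and tract-based lesion-symptom mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel- and tract-based lesion-symptom mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractvlsm)
```

## The analysis model

`tractvlsm` asks two questions of a cohort of patients with binary lesion
maps (white matter lesions, WML; lacunar lesions, LL) co-registered to one
voxel grid, and cognitive test scores:

1. *Where* does lesion status relate to cognition? — a mass-univariate voxel
   screen (VLSM).
2. *How much* does lesion volume inside a specific white matter tract
   explain, beyond total lesion burden? — a hierarchical ladder of nested
   linear models.

### Stage 1: voxelwise screen

Cognitive outcomes are composite domain z-scores: each subtest is oriented so
higher = better (timed and error-count subtests are multiplied by −1),
z-scored against the analysis sample itself (the package deliberately uses no
external norms, since inference is within-cohort), and averaged within
domain. Before the voxel screen the composites are residualized by OLS on
age, sex, education and a reading-test score, so the voxel tests operate on
covariate-adjusted scores.

At each voxel affected in at least `min_patients` patients (default 5; the
comparison is inclusive, so exactly 5 qualifies) a pooled-variance Student
t-test compares adjusted scores between lesioned and intact patients, with
the sign convention t = (mean intact − mean lesioned)/SE, i.e. positive t =
deficit. Voxels below the prevalence threshold are never tested: they define
the multiplicity family. Design choices here:

* **Pooled variance rather than Welch** (df = n₀ + n₁ − 2), the classical
  VLSM convention; Welch is available via `var_equal = FALSE`.
* **One-sided p-values in the deficit direction** by default, because only
  the deficit tail is thresholded and rendered downstream; `alternative =
  "two.sided"` switches both the p-values and the subsequent FDR step. The
  convention used is recorded on every result object.
* **Zero-pooled-variance voxels** have no defined t; they are dropped from
  the map (not set to 0) with a warning and a count on the result.

FDR control is Benjamini–Hochberg over the p-values of all eligible voxels
of the class being tested: with sorted p(1) ≤ … ≤ p(m), the cutoff is p(k),
k = max{i : p(i) ≤ i·q/m}, with no rejections when no such i exists. The
result also reports the *equivalent t threshold* (the smallest t among
significant voxels), so "significant" is exactly {t ≥ t-cutoff}. Surviving
voxels are grouped by 3D connected components; the default connectivity is
26 (faces, edges and corners — the most permissive standard rule) and is
configurable (6/18/26) because published analyses rarely state it.

### Stage 2: tract selection, volumetry and the ladder

A probabilistic tract atlas is thresholded at 0.1 (inclusive ≥; the boundary
convention is documented because "thresholded at 0.1" alone does not fix it).
A tract is *selected* when it contains **more than 50** significant voxels or
a **single cluster of more than 5** voxels overlapping it — both strict
inequalities. Clusters are labelled on the global significance map and then
intersected with each tract, because the screening question is whether a
coherent significant region projects onto the tract; re-clustering within
the tract is available via `recluster = TRUE`. Whether a count rule should
use a dilated neighbourhood rather than strict intersection is ambiguous in
the field; strict intersection is implemented.

Regional volumes are |lesion ∧ tract mask| × voxel volume, in ml of template
space ("normalized volumes"). Overlapping tract masks are allowed — real
probabilistic atlases overlap — and volumes are computed independently per
tract, consistent with the per-tract models of the ladder.

The ladder fits 12 models of the domain composite (not the residuals — the
covariates re-enter here as model terms):

| label | predictors |
|---|---|
| 1 | age + sex + education + reading test |
| 2a, 2b, 2c | model 1 + LL presence / + total WML volume / + both |
| 3a–3d | model 1 + one regional volume (LL, then WML, per tract) |
| 4a–4d | model 2c + one regional volume (LL, then WML, per tract) |

LL presence is a 0/1 indicator regardless of lesion count; volumes enter in
ml untransformed, so B is in z-score per ml. ΔR² for 2a–2c and 3a–3d is
tested against model 1; for 4a–4d against model 2c. The "previous model" for
2c is taken to be model 1 (so its ΔR² spans both burden terms), which is the
reading consistent with reporting one increment for the pair. The partial F
is computed from the R² identity F = (ΔR²/k)/((1 − R²_ext)/df_ext) and is
verified in the tests against `anova()` refits. CIs are t-based at a fixed
95%; no robust errors. Missing data are handled by listwise deletion before
any fit, so all 12 models share one sample — a prerequisite for nested-R²
comparisons.

Degenerate inputs: a lesion term with zero variance in the analysis sample
(e.g. regional LL volume in a cohort with virtually no lacunes) cannot be
estimated; the affected models are fitted without it, their increment over
the base is zero by construction and reported with p = NA, and a message
names the dropped term. Similarly, a lesion class for which no voxel reaches
the prevalence threshold skips the voxel screen with an explicit log entry
while volumetry and the ladder still run — sparse lacunar cohorts are the
expected, not the exceptional, case.

## The synthetic cohort generator

No patient lesion maps can ship with the package, so `sim_config()` /
`simulate_cohort()` generate cohorts with known ground truth. What it
emulates, and how:

* **WML**: a per-patient Gaussian random field (separable truncated-Gaussian
  smoothing, kernel scale `smoothness` voxels) is standardized exactly to
  unit marginal variance using the closed-form per-voxel SD of the smoothed
  noise, then thresholded at the quantile implied by the per-voxel lesion
  probability `base_prob` × a spatial profile × a lognormal unit-mean
  per-patient burden multiplier (`burden_sdlog`). This yields confluent,
  spatially correlated lesions with *exact* per-voxel marginal prevalence
  (verified against binomial bounds in the tests) and a realistic
  heavy-tailed volume distribution. The default profile concentrates
  prevalence towards the grid centre, mimicking periventricular
  predominance; a flat profile is available for calibration studies.
* **LL**: per-patient Poisson(`rate`) spheres of `radius` voxels (default 2
  voxels = 8 mm diameter at 2 mm voxels, within the 3–15 mm lacune
  definition), centres drawn from a mixture of a uniform background and
  per-tract Gaussians (SD = `dispersion` × tract radii) — lacunes cluster
  within a vascular territory rather than tiling a tract. Overlapping
  spheres union. An optional `wml_coupling` exponent ties the LL rate to the
  WML burden multiplier; the default is 0 (independent) since the dependence
  structure between the two classes is not established.
* **Covariates**: age 56.7 (SD 9.4) years, 82% male, 8-level ordinal
  education (uniform by default), reading score 100 (SD 12) — the
  demographic profile of a manifest-arterial-disease cohort.
* **Cognition**: one latent score per domain = covariate effects + Σ(planted
  per-tract coefficient × true regional lesion volume) + N(0, noise_sd);
  subtests are affine transforms with realistic means/spreads, lower-better
  subtests emitted inverted. True regional volumes use the same atlas
  threshold as the analysis (0.1).
* **Determinism**: one master seed; per-patient and per-stage sub-seeds are
  derived deterministically, so identical configurations are bit-identical
  and partial regeneration is reproducible.

### The reference scenario and its calibration

The `sim_config()` defaults define the package's reference recovery
scenario: n = 200 patients, 24 × 24 × 12 grid of 2 mm voxels, two disjoint
ellipsoidal tracts, a planted LL effect of **−3 z/ml in tract A and 0 in
tract B**, no WML effects. Three calibration choices were made once, at
design time, and matter for interpretation:

* **Unit latent variance.** noise_sd = 0.81 was chosen analytically so that
  covariate variance (≈0.12) + lesion-effect variance (≈0.23 under a
  compound-Poisson approximation) + noise ≈ 1. Because composites are
  z-scored against the sample, fitted coefficients are in units of the
  *composite* scale; with unit latent variance that scale coincides with the
  planted z/ml units. The approximation treats lacune volumes as additive;
  overlapping lacunes make the realized latent SD slightly below 1, so
  recovered coefficients run ≈5% large in magnitude — well inside the CI
  half-width at this n, and nominal CI coverage is preserved.
* **Executive subtests carry no subtest-level noise** by default (loadings
  1, noise 0): all residual variance lives in the latent noise term, so the
  composite is an exact affine image of the latent score and planted
  coefficients are not attenuated. Subtest noise is available (and used for
  the other domains) but any nonzero value attenuates coefficients by the
  usual reliability factor — a property of composite scoring, not of the
  estimator.
* **Placement concentration.** With dispersion 0.5 and rate 0.8, central
  tract voxels are lesioned in ~8–15 of 200 patients, comfortably above the
  5-patient eligibility rule, which is what gives the voxel screen its
  power in this scenario. A pilot sweep at design time showed that spreading
  placement over the whole tract leaves per-voxel counts straddling the
  eligibility threshold and makes the screen unstable.

### What the generator does not emulate

MRI intensities, acquisition artifacts, segmentation error, registration
error, brain atrophy, cortical/territorial infarcts, anatomically shaped
tracts, and any dependence of covariates on lesion burden (no confounding:
age is independent of lesion volume by construction, unlike in real
cohorts). Passing the recovery tests therefore demonstrates that the
*statistical machinery* is correct and calibrated under the stated
generating model — not that the pipeline is robust to registration or
segmentation failure modes of real data.

## Validation studies and problem sizes

The test-suite and `scripts/acceptance.R` validation studies use sizes
chosen to make Monte-Carlo error small while keeping a laptop-scale runtime:
a 500-patient, 48 × 48 × 24 cohort for the voxelwise oracle sweep (every
eligible voxel against `stats::t.test`, tolerance 1e-10); 1,000 random
p-vectors of length up to 10,000 for the BH oracle; 200 replicate
global-null cohorts (n = 200, 16 × 16 × 8) for empirical FDR control; 100
random sparse 16³ masks × three connectivities for the cluster oracle; and
100 replicates of the reference scenario for CI coverage and selection
power. With 100 replicates, an empirical coverage proportion has a binomial
SD of ≈2.2 points around 95% — observed coverage a couple of points off 95
is expected noise, not miscalibration.

## Known limitations

* The voxel screen tests lesion *status*, not lesion load, at a voxel, and
  inherits the usual VLSM caveats (spatial autocorrelation of lesions means
  significant voxels are not independent evidence; coverage is limited to
  voxels above the prevalence floor).
* BH-FDR control under the positive dependence induced by overlapping
  lesions is standard practice and empirically calibrated here, but is not a
  finite-sample guarantee for arbitrary dependence.
* The ladder is a fixed, confirmatory model sequence; it performs no
  selection or shrinkage, and cross-tract comparison of coefficients is out
  of scope.
* Education enters as a single numeric 1–8 term (one coefficient), not
  dummy-coded; this is configurable upstream of the ladder but is the
  reporting convention adopted throughout.
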