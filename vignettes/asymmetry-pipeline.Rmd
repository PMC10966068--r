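---
title: "Methods: learning CNV-specific brain asymmetry patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning CNV-specific brain asymmetry patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Recurrent copy number variants (CNVs) — deletions and duplications at the
1q21.1, 15q11.2, 16p11.2, and 22q11.2 loci — are among the strongest known
genetic risk factors for neurodevelopmental disorders, and they are
clinically associated with lateralized functions, speech and language above
all. `asymkit` implements a case-control workflow for asking how such
mutations reshape *structural brain asymmetry*: the left-right imbalance of
regional gray-matter volumes. The unit of analysis is a cohort table with
one row per subject (controls plus carriers of one of eight CNV classes),
covariates (age, sex, scanning site), and paired left/right volumes for 65
homologous region pairs (48 cortical, 7 subcortical, 10 cerebellar).

## Asymmetry index

For each homologous pair the asymmetry index is

$$\mathrm{AI} = \frac{L - R}{(L + R)/2},$$

a dimensionless quantity in $(-2, 2)$ for positive volumes; positive values
mean leftward asymmetry. The AI is invariant to global volume rescaling,
which is the main reason we do **not** residualize AI on intracranial
volume, age, or sex: multiplicative size effects cancel in the ratio, and
the per-hemisphere raw-volume analyses (which do need those covariates) use
a separate adjustment path (`covariate_adjust_volumes()`).

Order of operations: volumes are first adjusted for scanning site
(`adjust_site()`: least squares on site indicators, grand mean retained,
fitted jointly over all subjects — a message flags site-by-group imbalance,
where a joint fit can absorb group signal), then AI is computed, then AI is
z-scored. Two z conventions serve two purposes:

* `control_z` — per-region standardization by the control mean and SD, so
  every group is expressed in control-referenced units. Used for the
  univariate Welch *t*-tests with Benjamini–Hochberg correction across the
  65 regions of one contrast.
* `pooled_z` — standardization over exactly the subjects entering a model
  fit (the target CNV group plus controls). Used for all discriminant fits.

Sample SDs (n−1) are used everywhere.

## Discriminant patterns

Each CNV gets a dedicated two-class linear discriminant model on the 65
pooled-z asymmetry indices. The coefficient vector is the closed form
$\hat\Sigma^{-1}(\hat\mu_{\mathrm{case}} - \hat\mu_{\mathrm{control}})$ with
$\hat\Sigma$ the pooled within-class covariance. Because 65 features meet
carrier groups as small as 22, $\hat\Sigma$ is shrunk toward its diagonal
with an analytically chosen intensity (a Schäfer–Strimmer-style estimator
computed on the pooled within-class-centered rows; `shrinkage =` overrides
it). A singular covariance at zero shrinkage falls back to a minimal ridge
with a warning. Discriminant scores are evaluated in sample and summarized
by the rank-statistic ROC AUC; an optional stratified split is deliberately
out of scope — the models are interpretation devices, not deployed
classifiers.

A discriminant direction is only identified up to reflection. Every fitted
vector is therefore **canonically oriented** to correlate non-negatively
with the per-region Cohen's d map of the same contrast
($d = (\bar x_1 - \bar x_2)/\sqrt{(s_1^2 + s_2^2)/2}$, sample SDs), and the
same alignment rule is applied to every bootstrap draw.

### Bootstrap significance

`bootstrap_significance()` refits the model on B = 1000 resampled cohorts,
aligns each draw's sign against the full-sample d map, and flags a region
when the 2.5/97.5% percentile interval of its 1000 aligned coefficients
excludes zero. Resampling is stratified by class at the original sizes — a
plain pooled resample risks draws with a missing class; an unstratified
mode (`stratified = FALSE`) redraws such cases instead. Draws containing a
zero-variance region are refit at full shrinkage with a small ridge rather
than discarded, so B is exact and deterministic given the seed.

### Multiclass model

`fit_multiclass_lda()` solves the eight-class problem in one model:
eigen-decomposition of the within-class-whitened between-class scatter
(same shrinkage machinery), yielding classes − 1 = 7 axes ordered by
discriminability. The leading two axes are the plotting coordinates for
region loadings; on a two-class input the single axis is collinear with the
two-class fit, which the tests verify.

## Comparing patterns across CNVs

Pairs of 65-coefficient maps are compared by Pearson correlation. Spatial
autocorrelation makes parametric p-values for map similarity anticonservative,
so empirical p-values come from a **spin permutation** null: each spin draws
one uniform random rotation of SO(3) (normalized Gaussian quaternion),
applies it to the left-hemisphere cortical centroids — the mirror conjugate
acts on the right hemisphere, which for a mirror-symmetric atlas yields the
identical reassignment — and gives every cortical region the value of its
nearest rotated neighbor (duplicates allowed; ties break to the lowest
region index). Spherical rotation has no geometric meaning for subcortex
and cerebellum, so those regions are permuted uniformly within tissue
class. The empirical p is two-sided with add-one smoothing,
$p = (1 + \#\{|r_{\mathrm{null}}| \ge |r_{\mathrm{obs}}|\})/(1 + n_{\mathrm{spin}})$,
bounded below by $1/(n_{\mathrm{spin}}+1)$. Pairwise p-values are BH-FDR
corrected; patterns are also summarized by Ward (`ward.D2`) hierarchical
clustering on Euclidean distances between coefficient vectors.

## Functional decoding

Coefficient maps are annotated against term × region activation tables
(user-supplied, or synthetic via `generate_term_maps()`; redistributing a
meta-analytic database is out of scope). Two modes:

* **Correlation decoding** — the absolute coefficient is mirrored onto both
  hemispheres and Pearson-correlated with each term map; terms are ranked
  by similarity.
* **Binned weighted-score decoding** — the *signed* map assigns $+c$ to the
  right-hemisphere unit and $-c$ to the left (so hemispheric direction
  survives bilateralization). Units are ranked by signed coefficient and cut
  into 20 five-percentile bins; per term, activation is averaged within each
  bin, z-scored across the 20 bins, thresholded at z < 0.5, and multiplied
  by the bin's mean coefficient; the term's location on the spectrum is the
  score-weighted mean bin index.

Decoding choices that were genuinely open: bins aggregate by **mean** (not
sum), which is stable when bin sizes differ; with 130 units the 10 leftover
units are assigned palindromically (bins 1, 20, 2, 19, …), which makes bin
sizes symmetric so that negating the map maps a location L exactly to
21 − L; coefficient-rank ties break by unit index for determinism. Terms
whose thresholded bins are all zero (e.g. spatially uniform activation)
have no defined location and are flagged. Locations are meaningful when a
term's score profile is dominated by one sign of the spectrum; mixed-sign
profiles can produce unstable weighted means and should be read via the
per-bin scores instead.

## The synthetic cohort generator

Real clinical and biobank volumes cannot be redistributed, so every stage
is exercised on synthetic cohorts with known structure
(`synthetic_spec()` / `generate_cohort()`):

* Volumes are lognormal (positivity is required by the AI denominator) with
  a default coefficient of variation of 0.12 and a within-pair L/R log-scale
  correlation of 0.9, giving control AI a realistic spread of
  $\sqrt{2(1-\rho)\log(1+\mathrm{cv}^2)} \approx 0.054$.
* Planted effects are expressed in control-SD units of AI and applied by
  shifting the left log-volume (configurable to right or both), matching
  the left-dominant effects this analysis is designed to detect.
* Site effects are additive per-(site, region, hemisphere) constants — the
  simplest model the linear site adjustment removes exactly.
* Default group sizes mirror a realistic multi-site CNV cohort: 290
  controls and 32/27/110/144/82/69/66/22 carriers across the eight CNV
  classes.
* Covariates are independent of volumes (uniform age over 6–73 years, 55%
  male, uniform site assignment).

What the generator does **not** emulate: between-region covariance (regions
are independent given site), covariate–volume confounding, heavy-tailed
site or scanner artifacts, and any genuine biology of the planted regions.
Passing calibration tests therefore shows that the *procedures* are correct
and calibrated under their stated assumptions — not that real data meet
those assumptions.

Per-region volume variances are not published for the motivating cohorts;
the defaults above are stipulated once as field-plausible values and are
not tuned.

## Numerical and design choices

* Welch (unequal-variance) t-tests by default; Student's available via
  `var_equal = TRUE`. The FDR family is the 65 regions within one contrast.
* `fdr_correct()` rejects at adjusted p ≤ q (step-up boundary convention).
* All randomized routines take an explicit integer seed, consume one
  documented RNG stream in fixed order, and restore the caller's RNG state;
  reruns are byte-identical (the pipeline manifest records md5 sums).
* Degenerate inputs fail loudly: nonpositive volumes, zero reference SDs,
  single-class AUCs, zero-variance correlations and missing atlas regions
  are errors, not silent NAs; single-subject sites and constant term maps
  are warnings with well-defined passthrough/skip behavior.

## Study sizes used by the test suite

The packaged simulation studies run at sizes chosen to give stable Monte
Carlo estimates while staying comfortably reproducible on a laptop: null
calibration of the bootstrap flags uses 50 replicate cohorts of 60 carriers
/ 200 controls at B = 1000 (nominal 5% flag rate, accepted band 2–9% to
absorb percentile-CI small-sample deviation); power uses 25 cohorts with a
planted 1.0-SD shift; spin calibration uses 200 independent map pairs
against a 1000-spin null; decoding recovery uses 20 replicates. The
acceptance script (`scripts/acceptance.R`) recomputes all of these from
scratch at the same sizes.

## Known limitations

* In-sample AUCs are optimistic for small carrier groups; they are reported
  for pattern interpretation, not as generalization estimates.
* The spin null treats the cortical sheet as a sphere of parcel centroids;
  parcel size and spatial autocorrelation structure beyond centroid
  geometry are not modeled (variogram-matching nulls are out of scope).
* Percentile bootstrap intervals need not contain the point estimate in
  pathological cases and can under- or over-cover at small B or extreme
  skew.
* The joint site fit assumes approximate site-by-group balance; strongly
  confounded designs need an external harmonization step.
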