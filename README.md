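# asymkit

Multivariate structural brain asymmetry patterns in copy number variant
(CNV) cohorts.

## What this solves, and for whom

Recurrent CNVs — deletions and duplications at the 1q21.1, 15q11.2,
16p11.2, and 22q11.2 loci — are high-effect-size genetic risk factors for
neurodevelopmental disorders, clinically tied to lateralized functions such
as speech and language. For neuroimaging-genetics researchers with
case-control morphometry data, `asymkit` provides the full analysis chain
for asking how these mutations shift **structural brain asymmetry**, from
paired regional gray-matter volumes to functionally annotated,
statistically vetted asymmetry signatures.

The core quantities:

* **Asymmetry index** per homologous region pair:
  `AI = (L − R) / ((L + R) / 2)`, positive = leftward asymmetry.
* **Per-CNV discriminant pattern**: the 65-coefficient linear discriminant
  direction `Σ̂⁻¹(μ̂_case − μ̂_control)` on pooled-z asymmetry indices, with
  the pooled within-class covariance shrunk toward its diagonal
  (analytically chosen intensity) and the vector oriented to correlate
  non-negatively with the region-wise Cohen's d map
  `d = (x̄₁ − x̄₂) / √((s₁² + s₂²)/2)`.
* **Sign-aligned bootstrap significance**: B = 1000 stratified refits, each
  draw reflected to align with the full-sample d map; a region is
  significant when its 2.5/97.5% percentile interval excludes zero.
* **Multiclass discriminant** across all eight CNVs (classes − 1 = 7 axes).
* **Spin-permutation tests** for pattern-pair correlations: uniform random
  rotations of cortical parcel centroids on the sphere (mirror-conjugate on
  the right hemisphere), within-class permutation for subcortex/cerebellum,
  two-sided empirical p with add-one smoothing, BH-FDR across pairs; Ward
  clustering of the patterns.
* **Functional decoding** against term × region activation tables:
  absolute-map correlation ranking, and a signed 20-bin weighted-score
  procedure that locates each term along the coefficient spectrum.

A synthetic-cohort generator with planted per-region effects makes the
whole pipeline testable without access to clinical data.

## Worked example

```r
library(asymkit)

atlas <- default_atlas()   # 65 pairs: 48 cortical, 7 subcortical, 10 cerebellar

spec <- synthetic_spec(
  n_control = 200, n_per_cnv = c("16p11.2del" = 80),
  effect_map = list("16p11.2del" = c(
    planum_temporale = 1.0,                     # +1 control-SD leftward shift
    temporal_fusiform_cortex_posterior = -0.6)),
  seed = 42)
cohort <- adjust_site(generate_cohort(spec, atlas), atlas)

am_raw <- compute_asymmetry(cohort, atlas)
am_fit <- zscore_ai(subset_asymmetry(am_raw, c("16p11.2del", "control")),
                    "pooled_z")

fit <- fit_lda(am_fit, "16p11.2del")
fit
#> LDA asymmetry pattern: 16p11.2del vs control (n = 80 / 200)
#>   in-sample AUC 0.866, shrinkage 0.984
#>   strongest |coefficients|: planum_temporale (0.99),
#>   temporal_fusiform_cortex_posterior (-0.65), ...

boot <- bootstrap_significance(am_fit, "16p11.2del", B = 1000, seed = 7)
boot
#> bootstrap of LDA coefficients: 16p11.2del vs control, B = 1000
#>   6/65 regions significant (95% percentile CI excluding 0)

tests <- ai_group_tests(zscore_ai(am_raw, "control_z"), "16p11.2del")
head(tests[order(tests$p_fdr), c("region", "t", "p_fdr", "direction")], 2)
#>                               region         t        p_fdr direction
#> 46                  planum_temporale  6.926781 8.109588e-09  increase
#> 38 temporal_fusiform_cortex_posterior -4.585549 3.270052e-04  decrease
```

The two planted regions dominate the learned pattern (coefficients 0.99 and
−0.65 on the pooled-z scale), survive the sign-aligned bootstrap, and are
the only FDR-significant univariate shifts — `increase` meaning a leftward
asymmetry gain relative to controls, `decrease` the reverse. The realized
Cohen's d of the planted planum temporale AI shift is 0.91, close to the
planted 1.0.

For the end-to-end run (all groups, similarity, clustering, decoding, and a
reproducibility manifest):

```r
cfg <- run_config(synthetic = demo_synthetic_spec(seed = 1),
                  B_bootstrap = 1000, n_spin = 1000, seed = 1,
                  out_dir = "results")
run_pipeline(cfg)
```

or from the shell: `Rscript inst/cli/asymkit.R run --spec spec.yaml
--out-dir results --seed 1`.

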