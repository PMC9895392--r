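# metagdf15

Random-effects meta-analysis of growth differentiation factor 15 (GDF-15)
expression in gestational diabetes mellitus (GDM), packaged as a reusable
two-arm continuous-outcome meta-analysis toolkit for R.

## Who this is for

Epidemiologists and biostatisticians combining small two-arm studies that
report per-arm sample size, mean and SD (or medians/quartiles needing
conversion) on incompatible measurement scales — here, GDF-15 measured as
mRNA across expression platforms and tissues, and as serum protein across
assays. The study-level summaries of the GDF-15/GDM combined analysis
(13 expression-dataset rows, 7 article rows; 789 GDM patients and 1202
non-GDM pregnant controls in total) ship with the package as plain-text
fixtures.

## The statistics

* **Effect size**: Cohen's d, `d = (mean_case − mean_control) / s_pooled`,
  variance `(n1+n2)/(n1·n2) + d²/(2(n1+n2))`; Hedges' g optional. Sign
  convention: GDM minus control.
* **Pooling**: inverse-variance fixed effect, and DerSimonian–Laird random
  effects with `τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`, weights
  `1/(v + τ²)`, normal-approximation CIs; heterogeneity as Q, I², τ².
* **Publication bias**: Begg rank correlation (continuity-corrected Kendall
  z) and Egger regression (intercept t test on k−2 df).
* **Sensitivity**: leave-one-out re-pooling and restriction to studies that
  excluded preeclampsia/confounding conditions.
* **Summary conversion**: Luo optimal-weight mean estimators and Wan SD
  estimators for median/IQR/range reports.
* **Validation**: a seeded synthetic-study generator reproducing the
  random-effects model end to end (parameter recovery, CI coverage,
  bias-test operating characteristics).

See `vignettes/gdf15-meta-analysis.Rmd` for the full methods account.

## Worked example

Pool the four late-pregnancy serum-protein studies:

```r
library(metagdf15)
studies <- load_gdf15_fixture("protein", "late")
eff <- compute_effects(studies)          # Cohen's d per study
dersimonian_laird(eff)
```

```
Random-effects (DerSimonian-Laird) pooling of 4 studies
  pooled = 0.824, 95% CI [0.316, 1.331], se = 0.259
  Q = 19.119 (df = 3), I2 = 84.3%, tau2 = 0.215
```

GDF-15 protein is about 0.82 pooled SDs higher in GDM than in controls
(95% CI 0.32–1.33, excluding zero), with substantial heterogeneity
(I² = 84%) absorbed by the random-effects weights. The forest-table data
behind the plot:

```r
render_forest_table(dersimonian_laird(eff), eff)
```

```
            study_id estimate ci_low ci_high weight_percent
1               Tang    0.819  0.566    1.07           28.9
2           Banerjee    1.908  1.186    2.63           19.1
3              Yakut    0.668  0.218    1.12           25.0
4           Jacobsen    0.207 -0.145    0.56           27.0
5 Pooled (random_DL)    0.824  0.316    1.33             NA
```

No evidence of small-study bias in this stratum (`eggers_test(eff)`:
intercept 2.80, p = 0.57; `beggs_test(eff)`: S = 2, p = 0.73).

One call reruns every packaged analysis and compares with the published
values:

```r
reproduce_paper()$comparison
#                    analysis published computed abs_dev ...
# 1                 mrna_late      0.48   0.4857  0.0057
# 2               mrna_middle     -0.27  -0.2667  0.0033
# 3              protein_late      0.82   0.8237  0.0037
# 4            protein_middle      0.53   0.5336  0.0036
# 5      restricted_mrna_late      0.61   0.6115  0.0015
# 6   restricted_protein_late      0.57   0.5725  0.0025
# 7 restricted_protein_middle      0.39   0.3934  0.0034
```

## Command line

```sh
inst/exec/metagdf15 pool --level mRNA --timing late --model dl \
    --output pooled.json --forest forest.csv
inst/exec/metagdf15 simulate --k 12 --seed 7 --output synthetic.csv
```

Subcommands: `convert`, `effects`, `pool`, `bias`, `loo`, `simulate`,
`oc`, `reproduce-paper`; global flags `--output`, `--seed`, `--log-level`.
JSON results carry the fields of the corresponding R objects
(`pooled`, `se`, `ci_low`, `ci_high`, `q_stat`, `df`, `i_squared`,
`tau_squared`, `weights`).

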