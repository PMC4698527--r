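# survoptimism

How much of a survival model's apparent performance is optimism?
`survoptimism` compares three ways of building a tree-based prognostic
model for right-censored data — the **saturated survival tree** (ST), the
**pruned survival tree** (PT) and the **random survival forest** (RSF) —
by fitting each on the training part of repeated 10-fold cross-validation
splits and measuring discrimination and calibration on *both* the training
and the held-out part. The spread between the two is the model's optimism,
and the package's headline result is its ordering: ST ≫ PT ≫ RSF ≈ 0.

It is aimed at biostatisticians and clinical epidemiologists who want a
transparent, fully reproducible implementation of the whole comparison:
the estimators, the models, the metrics and the experiment are all
exported functions with tests, driven by a calibrated synthetic generator
for an in-hospital acute myocardial infarction (AMI) cohort (607 subjects,
204 deaths, age 61.34 ± 13.46 y, nine binary risk factors and a 4-level
intervention).

## What is implemented

* **Estimators** — Nelson–Aalen cumulative hazard
  H(t) = Σ_{t_l ≤ t} d_l / Y_l per node ([`nelson_aalen()`]), Kaplan–Meier
  censoring survival Ĝ(t) = P(C > t) ([`km_censoring()`]), and the
  two-sample log-rank chi-square used as the split criterion
  ([`logrank_statistic()`]).
* **Trees** — exhaustive log-rank cutoff search ([`best_split()`]),
  saturated growth with ≥ 1 death per terminal node ([`grow_tree()`]),
  terminal-node CHF prediction ([`predict_chf()`]), and pruning by the
  held-out error-versus-size curve ([`prune_tree()`]).
* **Forest** — bootstrap + per-node random variable subsets
  ([`grow_forest()`]), the out-of-bag ensemble CHF
  H\*(t|x_i) = Σ_b I_ib H_b(t|x_i) / Σ_b I_ib ([`oob_chf()`]), all-tree
  ensembles for new data ([`ensemble_chf()`]), and ensemble survival
  S = exp(−H) ([`ensemble_survival()`]).
* **Metrics** — mortality scores Σ_l H(t_l|x_i) ([`mortality_scores()`]),
  the pair-counting concordance index with its permissible-pair and
  tie-handling rules ([`c_index()`]), the IPCW Brier score
  ([`brier_score()`]), prediction error curves and the integrated Brier
  score IBS = (1/t_max) ∫ BS(t) dt ([`integrated_brier()`]).
* **Experiment** — repeated k-fold CV plans ([`make_cv_plan()`]), the full
  three-method study ([`run_study()`]), percentile-CI summaries with
  train-to-test percent change ([`summarize_records()`],
  [`percent_change()`]), and a saturated two-way ANOVA of method ×
  evaluation set on the replicate-level records ([`anova_two_way()`]).
* **Synthetic cohorts** — [`ami_profile()`] / [`generate_cohort()`], with
  an exact-count mode that reproduces every published categorical margin
  and the death count exactly.

Results are tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(survoptimism)

coh <- generate_cohort(ami_profile(exact_counts = TRUE), seed = 7)
study <- run_study(coh, repeats = 1, n_trees = 50, seed = 11)
study
```

```
Performance summary (mean [2.5%, 97.5%] across replicates):
# A tibble: 12 × 6
   method set   metric  mean lower upper
   <chr>  <chr> <chr>  <dbl> <dbl> <dbl>
 1 PT     test  cindex 0.638 0.538 0.692
 2 PT     test  ibs    0.233 0.189 0.286
 3 PT     train cindex 0.765 0.653 0.886
 4 PT     train ibs    0.131 0.108 0.153
 5 RSF    test  cindex 0.650 0.577 0.744
 6 RSF    test  ibs    0.212 0.183 0.244
 7 RSF    train cindex 0.624 0.602 0.639
 8 RSF    train ibs    0.205 0.195 0.211
 9 ST     test  cindex 0.554 0.426 0.651
10 ST     test  ibs    0.297 0.258 0.345
11 ST     train cindex 0.929 0.920 0.938
12 ST     train ibs    0.131 0.127 0.136

Train-to-test percent change:
# A tibble: 6 × 3
  method metric percent
  <chr>  <chr>    <dbl>
1 PT     cindex      17
2 PT     ibs         78
3 RSF    cindex      -4
4 RSF    ibs          3
5 ST     cindex      40
6 ST     ibs        127
```

Reading this: the saturated tree looks superb on its own training data
(C-index 0.93, IBS 0.13) and collapses on held-out folds (0.55, 0.30) — a
40% drop in discrimination. Pruning halves the damage. The forest's
out-of-bag "training" performance and its test performance are essentially
the same, i.e. its reported numbers generalize:

```r
glance(study)   # train - test gap per method
#>   method gap_cindex gap_ibs
#> 1 PT         0.127  0.102
#> 2 RSF       -0.0254 0.00692
#> 3 ST         0.375  0.166
```

`tidy(study$anova)` shows the same story as a model: the ST × train
interaction dominates (estimate 0.40, p ≈ 3e-14 here), while the set main
effect for the reference method (RSF on test data) is small and
non-significant. `autoplot(study)` draws the per-method training-versus-
test prediction-error curves.

At the published study scale use
`run_study(coh, repeats = 20, n_trees = 1000, seed = ...)`; the defaults
are a scaled-down profile of the identical code path.

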