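---
title: "Measuring the optimism of survival trees and random survival forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the optimism of survival trees and random survival forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A survival tree is an attractive clinical prognostic tool: it partitions
patients by covariate cutoffs into groups with visibly different survival,
and the partition reads as a decision rule. But the exhaustive cutoff
search that makes trees interpretable also makes their apparent (training
set) performance unusually optimistic. This package quantifies that
optimism by comparing three ways of building a tree-based survival model —
a saturated tree (ST), a pruned tree (PT) and a random survival forest
(RSF) — on both the data that built them and held-out data, under repeated
k-fold cross-validation.

The motivating setting is an in-hospital acute myocardial infarction (AMI)
cohort: follow-up is time from admission to death or discharge (days),
death in hospital is the event, discharge censors, and the predictors are
age, nine binary risk factors (sex, hypertension, hyperlipidemia, ischemic
heart disease history, diabetes, smoking, family history, pathologic
Q wave, streptokinase treatment) and a 4-level intervention factor. Since
no such registry is distributable, the package ships a calibrated synthetic
generator so that the entire pipeline is runnable and testable end to end.

## Models and estimators

**Per-node hazard.** Within any group of subjects $(T_i, \sigma_i)$ the
cumulative hazard function (CHF) is estimated by the Nelson–Aalen sum
$\hat H(t) = \sum_{t_l \le t} d_l / Y_l$ over the distinct death times
$t_l$, with $d_l$ deaths and $Y_l$ subjects at risk ($T_i \ge t_l$;
censorings tied with a death time stay in the risk set at that time —
the standard convention, which the source material leaves unstated).

**Saturated tree.** Nodes are split by the two-sample log-rank chi-square
statistic, searching every midpoint cutoff of every covariate (factors are
dummy-encoded into one indicator per level, so the 4-level intervention
contributes 4 columns and the full design has 14). A split is admissible
only if both children retain at least one death; splitting continues until
no admissible split remains, so every terminal node holds at least one
death and carries the Nelson–Aalen CHF of exactly its own subjects. A
subject is predicted by routing it to a terminal node ($x \le c$ goes
left, including exact ties) and reading off that node's CHF. Exactly tied
split statistics are resolved toward the lower variable index, then the
lower cutoff, so fits are reproducible. Zero log-rank variance (all deaths
where one side is absent from the risk set) is treated as statistic 0.

**Pruned tree.** Complexity is indexed by the minimum terminal-node size:
one tree is grown per value of a size grid (default
$\{1, 2, 3, 5, 8, 13, 21, 34, 55\}$, a near-geometric ladder reaching about
$n/10$ for the default cohort — no canonical grid exists for this
procedure), each still keeping one death per terminal node, and the tree
minimising held-out error $1 - C$ is selected, ties toward the smaller
tree. This reconciles the two available descriptions of the procedure —
error plotted against tree size, and against minimum terminal-node size —
because the size floor is what induces the tree-size axis;
cost-complexity pruning is deliberately not used. Selecting on the same
test fold that later evaluates the model leaks information in the pruned
tree's favour; we keep that protocol because it is the protocol being
studied, and note that it makes PT's reported test performance slightly
optimistic too.

**Random survival forest.** Each of $B$ trees is grown on a bootstrap
sample of size $n$ (samples with no events are redrawn so $B$ stays
fixed), and every node's split search sees a fresh uniform random subset
of `mtry` design columns. For training subjects the ensemble CHF averages
only the trees where the subject was out-of-bag (OOB),
$H^*(t \mid x_i) = \sum_b I_{i,b} H_b(t \mid x_i) / \sum_b I_{i,b}$; a
subject never OOB is excluded with a warning (error if more than 5% are).
New subjects average all $B$ trees. Averaging is pointwise on the union of
the member trees' jump times — a subset of the training death times, so
the grid stays small and no interpolation occurs. Ensemble survival curves
are $S = \exp(-H)$ of the averaged CHF; averaging CHFs and then
exponentiating differs (Jensen) from averaging the member survival curves,
and we adopt CHF averaging as the primary path because that is the form
the ensemble estimator is defined in; curve averaging can be built from
`predict_chf()` per tree if wanted. Defaults: `mtry = ceiling(sqrt(p))`
(= 4 for the 14-column AMI design — the field-standard default, since the
source only says "a limited number"), minimum terminal-node size 3 with at
least one death (full saturation of forest trees is neither stated in the
source nor standard practice).

**Concordance index.** Discrimination is measured by the pair-counting
C-index on mortality scores
$\mathrm{score}_i = \sum_{l=1}^{m} H(t_l \mid x_i)$ over the evaluation
set's unique death times. Pairs whose shorter time is censored, and
tied-time pairs with no death, are not permissible. Unequal-time pairs
count 1 when the shorter-lived subject has the higher score (0.5 on a
score tie); tied-time pairs with two deaths count 1 on a score tie and 0.5
otherwise; tied-time pairs with one death count 1 when the death has the
higher score and 0.5 otherwise. The printed description of these rules in
the source garbles some (in)equality signs; the implementation follows the
cited original definition, which its own worked arithmetic requires.
Score ties use absolute tolerance `1e-12` (floating-point summation
order).

**Brier score and IBS.** Calibration is measured by the
inverse-probability-of-censoring-weighted (IPCW) Brier score
$$\mathrm{BS}(t) = \frac1n \sum_i \left[
\frac{\hat S(t \mid x_i)^2 \, 1\{T_i \le t, \sigma_i = 1\}}{\hat G(T_i-)}
+ \frac{(1-\hat S(t \mid x_i))^2 \, 1\{T_i > t\}}{\hat G(t)} \right],$$
with $\hat G$ the Kaplan–Meier estimate of the censoring survival
function. The body of the score's defining display is unreadable in the
source, so the Graf decomposition from the literature it cites is used,
with the left limit $\hat G(T_i-)$ weighting past deaths. $\hat G$ is
estimated on the training part of each CV pair and reused for the test
part (the source is silent; training-based weights avoid test leakage).
Zero-weight contributors are dropped with a warning. The prediction error
curve evaluates $\mathrm{BS}(t)$ at the evaluation set's death times, and
the integrated Brier score is its exact time-average over
$[0, \max T_i]$: because the curve object *is* a right-continuous step
function, the integral is computed exactly as a rectangle sum rather than
by a trapezoid through the knots (a trapezoid would smear the jumps; on a
toy curve that is 0 before day 5 and 0.2 afterwards, the exact average
over 10 days is 0.1, which the rectangle sum returns).

**The study.** `run_study()` repeats k-fold cross-validation `repeats`
times (unstratified random partitions; a partition is redrawn, with a
warning, in the rare case a fold has no events), fits ST, PT and RSF per
training part, and records C-index and IBS on both parts — for RSF the
"training" record is the OOB ensemble, the honest analogue. Cell means
with empirical 95% intervals (2.5th/97.5th percentiles, linear
interpolation) and train-to-test percent changes (C-index: reduction
relative to training; IBS: increase relative to training; integer rounding
at magnitude ≥ 1, else 2 significant digits) are summarised per method,
and a saturated two-way ANOVA with dummy coding (reference cell: RSF on
the test set) tests method, evaluation set and their interaction on the
replicate-level records. Everything derives from one master seed: the CV
plan directly, each forest from `seed + 1009*rep + fold`, so runs are
reproducible end to end.

## The synthetic generator

The generator emulates the printed description of the motivating cohort:
607 subjects, 204 deaths, age mean 61.34 y (SD 13.46), and the published
marginal frequencies of the nine binaries and the intervention. Choices,
and what they imply:

* **Covariates are independent** across columns. Only marginals are
  published; no correlation structure is invented. Real AMI risk factors
  are correlated (e.g. diabetes with hypertension), so trees grown on
  synthetic data face an easier variable-selection problem than on
  registry data.
* **Age** is drawn from a normal truncated at 25 y (the cohort's
  eligibility floor). The pre-truncation location is solved numerically so
  the *post-truncation* mean equals the profile's `age_mean`; naive
  truncation of N(61.34, 13.46²) would bias the mean upward by ≈ 0.14 y.
* **Event times** are exponential proportional hazards,
  $\lambda_i = \lambda_0 \exp(\beta^\top x_i)$, with age standardised
  before its coefficient applies. Defaults give age (per SD) log-HR 0.5
  and pathologic Q wave log-HR 0.7 — moderate effects so grown trees have
  true structure to find — and the exponential form keeps the
  group-rate-ratio oracle analytic ($\mathrm{rate\ ratio} = e^\beta$).
* **Censoring** is an independent exponential "discharge" time with mean
  stay 7 days; $\lambda_0 = 0.0572$/day is calibrated (by the same
  expected-event-fraction bisection the exact-count mode uses) so the
  expected death fraction equals 204/607 ≈ 34%, i.e. ≈ 66% censored.
* **Exact-count mode** makes every categorical margin and the death count
  exact: each binary column is a permuted vector with `round(p·n)`
  (half-up) ones, the intervention's largest level absorbs the rounding
  remainder, $\lambda_0$ is re-tuned by bisection so the expected death
  count equals the target, and the 204 subjects with the smallest
  $\log E_i - \log C_i$ become the deaths (at the tuned hazard this
  threshold sits near 0, so it is the natural $\min(E_i, C_i)$ mechanism
  made exact).

Passing tests on this generator therefore show that the pipeline's
*relative* conclusions (gap ordering, chance-level nulls, calibration
arithmetic) are reproduced under a plausible data-generating process with
the published marginals — not that the original registry's absolute
numbers are recovered, which no synthetic stand-in can promise.

## Problem sizes and numerical choices

The package's default study profile is deliberately scaled down —
`repeats = 3`, `n_trees = 100` over 10 folds of the 607-subject cohort
(30 train/test pairs, 180 performance records) — and runs the identical
code path as the study scale (`repeats = 20`, `n_trees = 1000`, 1200
records); the scaled profile is what the test suite exercises. Other
numerical conventions: log-rank variance uses the hypergeometric form with
ties correction; bisection brackets the baseline hazard multiplicatively
and stops at relative width `1e-12`; percentile intervals use the
linear-interpolation order-statistic definition; degenerate inputs (no
events, empty groups, empty cells, no permissible pairs) raise typed
errors rather than returning silently.

## Known limitations

* Independent covariates and exponential times make the synthetic cohort
  smoother than registry data; absolute performance levels should not be
  read off it.
* The pruning protocol inherits the test-set leak of the procedure under
  study (by design).
* No competing risks, time-varying effects, missing-data handling,
  stratified/weighted log-rank variants, or variable-importance measures:
  none are part of the comparison being reproduced.
* OOB performance at small `n_trees` is noisier than test-set performance
  because each subject's ensemble averages only ≈ 37% of the trees.

## A worked run

```{r, eval = FALSE}
library(survoptimism)

coh <- generate_cohort(ami_profile(exact_counts = TRUE), seed = 7)
study <- run_study(coh, seed = 1)   # 3 x 10-fold CV, 100-tree forests
study                                # summary table with 95% intervals
glance(study)                        # train-test gap per method and metric
tidy(study$anova)                    # two-way ANOVA with interaction
autoplot(study)                      # prediction-error curves, one panel per method
```
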