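---
title: "Feature-selection workflows for omics tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-selection workflows for omics tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fsflow)
```

## Overview

`fsflow` composes feature selection for omics tables (samples × features)
out of three stages, each optional and each operating on the output of the
previous one:

* a **univariate relevance filter** that scores features against the
  outcome in isolation,
* a **multivariate redundancy filter** that looks only at dependencies
  among features, and
* a **wrapper** (recursive feature elimination) that scores candidate
  subsets by the cross-validated performance of the final learning model.

The guiding heuristic is the classical one: a good subset contains features
that are individually predictive of the outcome and mutually
non-redundant. Filters are cheap and model-agnostic, so they run first and
shrink the table by an order of magnitude or more; the expensive wrapper
then works on what remains.

## Data model

`feature_matrix()` is a numeric samples × features matrix with unique
sample and feature identifiers. Missing cells are allowed on input only:
`drop_incomplete_features()` applies feature-wise complete-case deletion
(any feature with one or more missing cells is removed) before any filter
runs. We deliberately do not impute — imputation quality is
dataset-specific and would silently enter every downstream score. Files in
either orientation (samples-as-rows, or the features-as-rows layout of GEO
series-matrix exports) are converted to the canonical samples-as-rows form
on read; class labels are opaque strings, so numeric 0/1 status columns
become categories in classification tasks.

## Univariate filtering

The default filter scores feature $j$ by $|r(x_j, y)|$, the absolute
Pearson correlation, with a binary outcome encoded $\{0, 1\}$ in class-level
order. Features with score **at or below** the cutoff (default 0.30) are
removed; the boundary is dropped, and the complementary redundancy filter
below treats *its* boundary as a violation, i.e. removal happens at
$|r| \le 0.30$ here and at $|r| \ge 0.75$ there. Constant features have
undefined correlation and are mapped to score 0 (and a `zero_variance`
tag) rather than raising an error, because degenerate columns are routine
in omics exports and should not abort a run.

Pearson rather than rank correlation is the default because the workflow
targets (log-scale) expression and physicochemical properties whose
relevant structure is linear; the choice is stated once and configurable.
The correlation filter refuses outcomes with more than two classes — a 0/1
encoding is no longer meaningful — and directs the user to the
information-gain filter, $IG_j = H(\mathrm{class}) -
H(\mathrm{class} \mid \mathrm{bin}(x_j))$ in bits. Discretization is
equal-frequency with $\lceil \sqrt{n} \rceil$ bins capped at 10: quantile
binning is insensitive to monotone transforms and the cap keeps
per-bin counts usable at typical omics sample sizes.

## Redundancy reduction

Two alternatives, chosen by whether downstream interpretation requires
original features.

**Correlation-matrix (CM) filter.** Greedy elimination: while any retained
pair has $|r| \ge 0.75$ (inclusive boundary), take the violating pair with
the largest $|r|$ and drop the member with the larger mean absolute
correlation against all currently retained features — the member more
redundant with everything else. Mean-correlation ties (within $10^{-12}$)
drop the later column, so earlier features win deterministically. The
post-condition (no retained pair at or above the cutoff) is asserted after
every call, the filter is idempotent, and a feature involved in no
violating pair is never touched. Zero-variance columns are an error here
(their correlation is undefined); run the univariate filter first, which
always removes them.

**PCA filter.** Principal components of the centered, unit-variance-scaled
matrix, keeping the smallest leading set whose cumulative explained
variance reaches 95% (default). Scaling is on by default because omics
features live on wildly different scales and unscaled PCA would be
dominated by high-variance features; it is configurable. Determinism
across platforms is forced by a sign convention (the largest-magnitude
loading of each component is positive), and components with a variance
ratio below $10^{-12}$ are treated as zero when counting rank — for $n$
samples at most $n - 1$ components can carry variance after centering.

A configuration placing the CM filter after PCA is rejected at validation:
component scores are pairwise uncorrelated by construction (a tested
invariant), so the step could never do anything, and a silently inert step
is a configuration bug.

## Recursive feature elimination

`rfe()` implements backward elimination with internal k-fold
cross-validation (default 10 folds, stratified by class; plain random
partitions for regression). Within each fold the features are ranked **on
the training part only** — random forests by impurity-decrease importance,
the radial SVM by the model-free absolute-correlation ranking (the radial
kernel exposes no per-feature weights; permutation importance is available
behind a flag but is quadratic in cost) — then for each candidate subset
size the model is refit on the top-$k$ features and scored on the held-out
part (accuracy, or RMSE for regression). The chosen size maximizes mean CV
accuracy (or minimizes RMSE); exact ties go to the **smaller** size,
implementing the workflow's parsimony goal. The final ranking and selected
set are recomputed on the full data.

The default size grid is powers of two from 1 up to and including the
current feature count: log-spacing bounds the number of model fits while
covering the small-subset region where the optimum typically lives. Sizes
exceeding the available feature count are pruned with a warning.

Model defaults: random forest with 500 trees; SVM with radial kernel,
kernel width $\gamma = 1 / (2 \,\mathrm{median}\, \lVert x_i - x_j
\rVert^2)$ (the median heuristic, computed on each training fold) and cost
10. Cost 1 was considered and rejected: with the median-heuristic width an
$\epsilon$-SVR at cost 1 visibly underfits even a noiseless linear signal
(training RMSE ≈ 0.25·sd(y) on $y = 2x_1$, versus ≈ 0.04·sd(y) at cost
10), which would make the wrapper's CV scores nearly flat in subset size.

Every model fit and fold assignment is seeded through a fixed counter
scheme derived from the run seed, and — less obviously — so is
*prediction*: `predict.randomForest` breaks majority-vote ties using the
global RNG, so fsflow seeds predictions from the fitted handle. Identical
seed and input therefore give bit-identical profiles, selections and
metrics files.

## Performance estimation

`evaluate_workflow()` estimates generalization over `n_splits` (default
20) randomized class-balanced train/test splits. "Class-balanced" is
implemented as stratified sampling preserving class proportions — the
conservative reading — with an optional `balance = "downsample"` mode that
equalizes class counts in training. The training fraction defaults to 2/3;
the original split proportions of the resampling protocol this follows are
not published, so the conventional choice is used and exposed as a
parameter. Per-split seeds are Lehmer-mixed from the master seed
(`split_seed = (seed · 48271 + i) mod 2147483629`), so any split is
reproducible in isolation.

Inside each split the **entire** workflow — missing-feature removal, every
filter, the RFE, the final fit — is re-run on the training part only; the
test part is touched exactly once, for prediction. Two tested leakage
properties follow: corrupting a fold's held-out samples never changes that
fold's RFE ranking, and perturbing a split's test samples never changes
that split's selected features.

Regression metrics are RMSE and $R^2$; $R^2$ is the squared Pearson
correlation between predicted and observed (the convention of the
resampling framework this protocol follows), with `r2_convention = "ss"`
switching to $1 - SSE/SST$. Constant predictions make the correlation
undefined; that is reported as $R^2 = 0$ with a flag and a warning rather
than an error. Per-step wall-clock time is recorded on the in-memory
result but excluded from the metrics JSON, which must be byte-identical
across equal-seed runs on any hardware.

## Synthetic data

`make_classification_data()` / `make_regression_data()` generate the
structure the workflow assumes, with ground truth attached:

* **informative** features: class $k$ draws $N(\mu_k, 1)$ with centered
  means separated by the standardized effect size $d$ (two classes:
  $\pm d/2$); for regression, $N(0,1)$ columns entering
  $y = X\beta + N(0, \sigma)$;
* **redundant** features: each is a noisy copy of exactly one informative
  parent (star topology, so proxy relations are checkable):
  $x_{copy} = \rho\, x_{parent} + \sqrt{1-\rho^2}\, \sigma_p\, \varepsilon$,
  where $\sigma_p$ is the parent's marginal SD. Scaling the innovation by
  $\sigma_p$ makes the population correlation exactly $\rho$ even when the
  parent carries a class effect (and hence has variance > 1) — the naive
  unit-variance innovation would overshoot the target correlation;
* **noise** features: $N(0,1)$, independent of everything;
* optional uniform missingness and a heavy-tail ($t_3$) noise flag.

Everything is drawn inside a single seeded block, so output is
byte-identical under a fixed seed.

What this emulates: the relevant/redundant/irrelevant block structure of
expression and property tables, at realistic desk-scale sizes. What it does
not: heteroscedastic mass-spec intensity noise, batch effects, correlated
noise cliques, class-dependent missingness. Passing tests on this
generator demonstrate the machinery's contracts (scores, eliminations,
leakage-freedom, determinism), not performance claims about any particular
real dataset.

## Study conditions and measured behavior

The test suite and `scripts/acceptance.R` use a fixed synthetic family as
their study condition: $n = 150$; 5 informative features at $d = 1.5$; 10
redundant copies at $\rho = 0.85$; 300 noise features; balanced classes.
At these sizes the full X2(0.30)–CM(0.75)–RFE–RF chain recovers ≥ 80% of
the informative signals (a parent or one of its copies) in well over 90%
of seeds while selecting under 4% of the features, and the complete suite
runs in minutes on one CPU.

One directional expectation does **not** hold on this family, and the
package reports it rather than hiding it: the selected-feature workflow
trails the no-selection random-forest baseline by about 2–5 accuracy
points (e.g. 90.4% vs 94.1% at one seed of the acceptance script).
Stage-wise measurement attributes the loss to the CM step. That is not a
bug — the CM output is verified against an independent greedy oracle — but
a property of the data model: at $d = 1.5$ each redundant copy carries
class signal with *independent* noise, and a random forest profits from
averaging over all fifteen signal-bearing columns, exactly the averaging
the redundancy filter removes. On real omics tables redundant features
share structured (technical, batch, co-regulation) noise, which is the
regime in which redundancy elimination pays. The reduction claim (> 90%
fewer features at broadly comparable accuracy) does hold here.

## Numerical conventions and edge cases

* Cutoff boundaries: univariate removal at $\le$ cutoff, CM violation at
  $\ge$ cutoff (both taken literally from their defining inequalities).
* CM tie-break: $10^{-12}$ tolerance on mean absolute correlations, later
  column dropped.
* PCA: rank tolerance $10^{-12}$ on variance ratios; sign fixed per
  component; explained-variance ratios sum to 1 within $10^{-9}$.
* Constant features: score 0 in the univariate filter, error in the CM
  filter, error under unit-variance PCA scaling.
* Empty kept-sets raise named errors carrying the best observed score, so
  callers can distinguish "cutoff too strict" from "no data".
* All package errors carry condition classes (`fs_config_error`,
  `fs_no_features_error`, ...) under `fsflow_error`; the CLI maps
  validation errors to exit code 2 and runtime errors to 1.

## Known limitations

* The correlation filter is linear; nonlinear univariate relevance needs
  the information-gain filter or an external score.
* The SVM wrapper's internal ranking is univariate (by design, for cost);
  it cannot discover purely interactive features. The random-forest
  wrapper can, at the price of importance-ranking noise.
* RFE's chosen size rides an argmax over a possibly flat CV curve; on
  saturated problems the parsimony tie-break matters more than the curve.
* No nested hyperparameter tuning: model defaults are fixed per run, and
  comparing pipelines statistically (beyond mean ± SD over splits) is out
  of scope.
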