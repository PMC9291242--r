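---
title: "Methods: connectome-based ideology prediction in ideoconn"
author: "ideoconn maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based ideology prediction in ideoconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ideoconn` predicts a 6-point liberal–conservative self-placement
(1 = Very liberal … 6 = Very conservative) from functional connectivity
(FC) matrices and then interrogates the fitted models: which tasks
predict, how the per-task scores relate to each other, whether FC adds
information over survey covariates, and which brain connections drive
the prediction. This vignette documents the model, its assumptions, the
tunable parameters, the synthetic world used for validation, and the
numerical and design choices made where the procedure was genuinely
open.

# From BOLD series to FC matrices

Inputs are ROI-averaged BOLD time series, one `T × R` matrix per
subject and task. Two preprocessing steps precede connectivity:

* **Task regression** (`regressOutTask`). Task-evoked activation is
  removed by OLS on an intercept plus a user-supplied `T × K` design
  matrix; each retained ROI column is replaced by its residual. The
  design is accepted as given — whether regressors are raw stimulus
  timings or HRF-convolved is upstream of this package. Rank-deficient
  designs are rejected rather than silently pseudo-inverted.
* **ROI exclusion** (`computeFC`). A column is excluded if it is
  entirely missing *or* has zero variance. Only the all-missing case is
  classical (a dead parcel, e.g. one ROI out of 269 yielding a
  268 × 268 matrix); the zero-variance extension is required because
  Pearson correlation is undefined there. Missing data are encoded as
  `NA`, never zeros, so exclusion logic is testable.

The FC matrix stores raw Pearson correlations in `[-1, 1]` with an
exactly zero diagonal; no Fisher-z transform is applied, matching the
convention that the matrix itself (not a variance-stabilized version)
is the network input. `assembleDataset` restricts all matrices to the
intersection of retained ROIs so dimensions agree across the cohort,
and original 1-based ROI indices are preserved in `roiLabels` so
excluded parcels remain traceable.

# The connectome regression network

The network maps an `R × R` FC matrix to a scalar score through:

1. per-edge input normalization (below);
2. an **edge-to-node (E2N)** layer of `F` cross-shaped filters,
   `H(i,f) = Σ_j [w_r(f,j)·E(i,j) + w_c(f,j)·E(j,i)] + b_f`;
3. very leaky ReLU, `f(x) = x` for `x ≥ 0`, `x/3` otherwise;
4. a **node-to-graph (N2G)** layer of `G` units fully weighting the
   `R × F` node features;
5. very leaky ReLU, then dropout at rate 0.5 (training only);
6. a linear output unit.

Training minimizes the Euclidean (mean squared) loss by minibatch SGD
with momentum. Design choices worth recording:

* **Depth.** Exactly one E2N and one N2G layer plus a linear head; no
  edge-to-edge layers. This is the minimal architecture containing both
  named layer types.
* **Row/column weights.** Since FC inputs are symmetric the two filter
  halves are redundant in expectation; both are kept to match the
  architecture, with `tieWeights` available to constrain them equal.
* **Input normalization.** "Minibatch normalization" is implemented as
  batch normalization of the vectorized edges: within each training
  minibatch every edge is centered and scaled by its batch statistics
  (no learned scale/shift). For evaluation the training-set statistics
  are stored in the fitted parameters, making evaluation-mode
  prediction a deterministic function of the input. The SD is floored
  at 1e-3 so constant edges (the diagonal) cannot divide by zero.
* **Targets** are the raw 1–6 Likert values treated as continuous;
  squared-error loss implies regression, and classification happens
  downstream by logistic models on the scores.
* **Stability.** The global gradient norm is clipped (default 5) each
  step; without clipping, momentum SGD at the upper end of the
  learning-rate range occasionally diverges on 40+-ROI inputs.
  Divergence that survives clipping (pathological learning rates)
  aborts with a diagnostic rather than returning garbage. Output bias
  is initialized at the training-target mean; weights are Gaussian with
  1/sqrt(fan-in) scale.

## Hyperparameters and random search

Optimizer settings are not architectural constants and live in a
`searchSpace`: filters `{16, 32, 64}`, N2G units `{8, 16, 32}`,
learning rate log-uniform on 1e-4…1e-2, epochs `{50, 100, 200}`, batch
size `{8, 16}`. `fitFold` draws `nDraws` seeded configurations, trains
each on the training fold only, and keeps the one with the lowest final
evaluation-mode training loss — tuning is per fold ("in each fold"),
never shared across folds, and never touches held-out data. Dropout
(0.5) and the leak slope (1/3) are fixed by the architecture and the
constructor refuses to change them.

## Out-of-fold scoring

`crossValidatedScores` partitions subjects into `k = 10` folds once and
reuses the partition for every task, so the per-task score columns are
comparable row by row. Fold assignment is a seeded uniform partition by
default (stratification by ideology available as an option). Every
score is produced while its subject was held out; the unit tests verify
this by recomputing each score from the stored fold model.

# Score analytics

* **Stratification.** Extreme = levels {1, 6}; moderate = {2, 3, 4, 5}.
* **Correlation tests.** The exact t-distribution test for a Pearson
  correlation is the default. A chi-squared score-type variant
  (`p = P(χ²₁ > n·r²)`) is available behind `method = "chisq"` because
  correlation significance is sometimes assessed that way in this
  literature; the t-test is preferred as the standard exact test.
* **Bonferroni.** `p_bonf = min(1, m·p)` with `m = 9` (one test per
  task) as the default family within each subgroup.
* **PCA.** Correlation-matrix PCA (columns standardized) via `prcomp`;
  task contributions to component m are squared loadings normalized to
  100%. Scaling is exposed as a switch; standardization is the default
  so that tasks contribute on equal footing regardless of score
  variance.

# Model comparison and importance

Dichotomization groups levels 4–6 as conservative, 1–3 as liberal.
Monte Carlo cross-validation draws, per sample, a test fraction
uniformly from (0.05, 0.50) and a random test set of that size; all
models are fitted on the identical training set and evaluated on the
identical test set, making the comparison paired. 1,000 samples is the
default. Choices the procedure leaves open, resolved here:

* "Statistically higher/indistinguishable" vs the Parent Conservatism
  benchmark is operationalized as disjointness of percentile 95%
  intervals of per-sample AUC; no distributional test is implied.
* Splits leaving one class in train or test are resampled (cap 100).
* Accuracy uses a 0.5 probability threshold.
* Complete separation in a logistic fit is flagged and falls back to a
  lightly ridge-penalized fit so probabilities remain usable.

`lassoImportance` standardizes features to unit variance, then picks
the penalty by k-fold cross-validated binomial deviance over glmnet's
path (minimum rule default; one-standard-error rule optional).
Importance is the absolute standardized coefficient — comparable across
predictors precisely because of the standardization, which is also why
the ranking is invariant to affine rescaling of raw features. The
unpenalized refit reports raw-scale coefficients with Wald SEs and
uncorrected p-values, mirroring how such tables are conventionally
presented.

# Gradient saliency

For each subject, the gradient of the evaluation-mode score with
respect to every input edge is computed by backpropagation through the
subject's *own out-of-fold model* — consistent with leak-free scoring; a
pooled variant averaging over fold models exists. The input
normalization is affine at evaluation, so its Jacobian (1/SD per edge)
is folded in and gradients refer to raw correlations. Gradients are
averaged over subjects into `G_t`, whose diagonal is zeroed (diagonal
entries are structurally fixed at zero in the input and are not edges).

* **Centrality** is `c(i) = Σ_j |G_t(i,j)|`.
* **Sign convention.** Higher score = more conservative (outcome coding
  1–6), so positive mean gradients mark conservative-predictive edges,
  negative liberal-predictive. The convention is stated here because
  nothing in the loss fixes it — it follows from the outcome coding.
* **Edge ranking** symmetrizes `G_t` first (`(G + Gᵀ)/2`): for a
  symmetric input the two orientations of an edge are not separately
  identifiable. Ties break to the lexicographically smallest `(i, j)`;
  a side with no strictly signed entry is returned as `NA` with a
  warning rather than inventing a winner.
* **Region aggregation** averages member-ROI centralities; a region is
  flagged as "statistically higher than average" when it exceeds the
  across-region mean by 1.645 SD (one-sided 95% under normality),
  configurable — the flagging rule is a package choice since no test is
  canonically defined for this quantity.
* **Atlas.** The packaged 269-ROI → 78-region table (ROI 252 excluded)
  is a *synthetic stand-in* with AAL-style region labels; the exact
  parcellation defining such a grouping is acquisition-specific. Users
  should substitute their own table for anatomical claims.

# The synthetic world

The generator's defaults state the cohort being emulated: 174 subjects;
ideology histogram 24/52/49/36/9/4 (assigned exactly, then shuffled by
seed); survey covariates with target ideology correlations of e.g.
0.417 (mother's conservatism), 0.349 (father's), 0.279 (religiosity);
nine tasks; 269 ROIs with ROI 252 all-missing available via
`missingRoi`.

* **Covariates** are drawn from a latent-Gaussian copula per covariate:
  `X = ρ'·z + sqrt(1−ρ'²)·ε` with `z` the standardized ideology, then
  discretized to the covariate's observed marginal (its printed Likert
  response distribution; ages follow a right-skewed discrete
  distribution on 18–40 with mean ≈ 21.4). Discretization attenuates
  correlation, so `ρ'` is pre-compensated by the analytically computed
  attenuation factor `corr(discretized, latent)`; realized correlations
  converge on the target as n grows (verified at n = 5,000 within
  ±0.05). Covariates are conditionally independent given ideology —
  only covariate–ideology correlations are part of the stated world;
  inter-covariate structure is deliberately not modeled and defaults to
  zero.
* **Planted FC signal.** Each signal edge `(i, j)` in task t receives a
  shared latent factor whose loadings give the pair a latent
  correlation `baseCorr + effect·z_k` for subject k. The construction
  is invertible and keeps unit marginal variances; configurations that
  push any correlation outside (−1, 1), or overload a node past unit
  variance, are rejected. Edges sharing a node induce a small product
  correlation between the node's other partners — acceptable for
  recovery tests, which use node-disjoint edges.
* **What the generator does not emulate:** hemodynamic response shapes
  (the optional task component is a plain design-matrix regression
  target), temporal autocorrelation of BOLD noise, head-motion
  artifacts, inter-covariate correlations, and spatial structure among
  ROIs. A green recovery test therefore establishes that the pipeline
  recovers planted linear edge–phenotype structure under white noise —
  not that it would behave identically on real scanner data.

`generateScoreMatrix` additionally simulates the *output* of the
network stage (score columns with chosen ideology correlations, on the
1–6 scale) so the downstream analytics can be tested in seconds without
training.

# Validation strategy and limitations

The test suite checks structural counts (268 × 268 after exclusion,
nine matrices per subject, 49/125 dichotomization), exact brute-force
oracles for both layer types, finite-difference agreement of the
saliency gradients (1e-4 relative, off-diagonal), null calibration
(no planted signal ⇒ per-task score correlations with median |r| < 0.2
over seeds and chance-level Monte Carlo AUC), planted-signal recovery
across the score, comparison, importance and saliency stages, the
Bonferroni and PCA identities, and byte-level determinism under fixed
seeds. Desk-scale runs use 40 ROIs, a one-draw search space, and
15–30 epochs so the whole suite stays within minutes; this scales the
search down, not the statistical structure.

Known limitations: gradient checks exclude the structurally zero
diagonal, where the floored normalization SD amplifies
finite-difference noise at activation kinks; training is single-thread
CPU R and targets hundreds, not tens of thousands, of subjects; the
packaged atlas is synthetic; and with four subjects in the most
conservative category at reference scale, extreme-subgroup correlations
are low-powered — a property of the stated world, not of the
implementation.
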