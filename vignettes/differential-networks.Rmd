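---
title: "Methods: joint common/differential network inference with ddnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint common/differential network inference with ddnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddnet)
```

## The model and its assumptions

`ddnet` estimates two condition-specific Gaussian graphical models with a
shared node set by neighborhood selection: node *i* is regressed on its
allowed predictors `A(i)` under both conditions simultaneously,

$$
L(i) = \sum_{c=1}^{2} \frac{1}{N_c}\,
  \lVert y_i^{(c)} - X_{A(i)}^{(c)} \beta_i^{(c)} \rVert_2^2
  + \sum_{j \in A(i)} \lambda_1(i,j)\,
    \bigl(|\beta_{ij}^{(1)}| + |\beta_{ij}^{(2)}|\bigr)
  + \sum_{j \in A(i)} \lambda_2(i,j)\, |\beta_{ij}^{(1)} - \beta_{ij}^{(2)}|,
$$

and an edge is drawn wherever a coefficient is nonzero. The fusion term
is what makes the *differential* network trustworthy: without it, two
independently-fitted sparse networks differ everywhere by sampling noise;
with it, coefficients are pulled exactly equal across conditions unless
the data support a difference.

Assumptions worth keeping in mind:

* **Linearity / Gaussianity.** Edges represent linear conditional
  dependencies. Heavy-tailed or strongly nonlinear relations are out of
  model (though condition-specific linear rewiring is itself a form of
  nonlinearity across the combined population).
* **Same feature set under both conditions**, no missing values, no
  zero-variance features — filtering and imputation are upstream steps.
* **Standardization convention.** Each feature is centered and scaled
  *per condition* with the population (divisor-$N$) variance, so
  $(1/N_c)\lVert x_j \rVert^2 = 1$ exactly. This makes the quadratic
  coefficient of the per-pair reduced objective exactly one, which the
  closed-form update requires; it is why `ddn_fit()` insists on
  `standardize()`d input rather than silently rescaling.

## The solver

Block coordinate descent cycles over predictors $j \in A(i)$ in ascending
index order. With all other coefficients fixed, the objective in the pair
$(a, b) = (\beta_{ij}^{(1)}, \beta_{ij}^{(2)})$ reduces to

$$
g(a,b) = a^2 - 2\rho_1 a + b^2 - 2\rho_2 b
  + \lambda_1 (|a| + |b|) + \lambda_2 |a - b|,
$$

with $\rho_c$ the inner product of predictor $j$ with the current
residual. $g$ is strictly convex and piecewise quadratic; its unique
minimizer is the stationary point of one of finitely many sign-pattern
regions (origin; fused $a=b$; $a=0$ or $b=0$; the interior orthants of
$(\operatorname{sign} a, \operatorname{sign} b, \operatorname{sign}(a-b))$).
`pairwise_update()` evaluates all twelve closed-form candidates and
returns the best, resolving ties toward the sparser and then the fused
solution so the algorithm is deterministic. Two independent checks back
this derivation in the tests: a grid-plus-refinement numerical minimizer,
and the fused-Lasso prox decomposition (fuse the pair first, then
soft-threshold), which reaches the same answer by a different route.

Numerical choices:

* **Convergence** is declared when the mean absolute change over the
  $2\,|A(i)|$ coefficients in a sweep drops below `tol` (default `1e-6`);
  `max_sweeps` defaults to 100000 and exhausting it flags the node as
  unconverged rather than failing.
* **Residual maintenance** is incremental per update, with a full
  recomputation every 50 sweeps to bound floating-point drift.
* **Warm starts**: sweeps and cross-validation reuse the previous
  solution along a descending $\lambda_1$ path. The problems are convex,
  so warm starting changes arrival time, never the solution.
* **Parallelism**: nodes are independent; `n_workers` forks over nodes
  and results are identical at any worker count.

Edges are extracted with the OR rule — pair $\{i,j\}$ is an edge in a
condition if either allowed direction is nonzero — with weight the mean
of the allowed $|\beta|$ values. OR (rather than AND) preserves edges
that are estimable in only one direction under directional constraints.
The binarization threshold defaults to 0 because the L1 penalty already
produces exact zeros.

## Constraints

`build_spec()` composes the allowed-predictor structure in three
precedence tiers: an all-allowed default, layer-pair rules in listed
order, then per-edge overrides. A *directed* allowed relation u→v sets
`allowed[v, u]` and clears `allowed[u, v]`, encoding known regulatory
direction; undirected rules set both. `mask_non_edges()` implements
constraint-strength experiments: it disallows a chosen fraction of
candidate pairs that are not true edges (both directions together, never
touching true edges), through a fixed seeded permutation so that masks at
increasing fractions are nested — which also makes the monotonicity
property testable.

## The synthetic-data generator

`simulate_scenario()` emulates the validation design: a
preferential-attachment (scale-free) graph on the mRNA layer (`m = 1`
edge per new node, giving a tree), regulator layers (TF protein, miRNA)
each wired to `regulator_out_degree = 5` uniformly chosen mRNAs, 25% of
template edges removed independently per condition, and 200 Gaussian
samples per condition drawn from each condition's GGM. Precision
matrices place uniform(0.2, 0.5) magnitudes with random signs on the
edges, set the diagonal to the absolute row sum plus 0.1 (strict diagonal
dominance, hence guaranteed positive definiteness), and rescale to unit
diagonal so partial correlations stay bounded. The weight range and
boost were chosen once so that edges are detectable but not trivial at
$n = 200$; an `intra_all_layers` flag adds scale-free wiring inside the
regulator layers for the all-layer topology variant. All randomness
flows from one master seed through documented sub-seeds
(`sample.int` substreams), so scenarios replay exactly.

What the generator does *not* emulate: count-data noise (negative
binomial, dropout), batch effects, unmeasured confounders, or hub-biased
regulator targeting. Passing the recovery tests therefore demonstrates
correctness of the estimator under its own model, not performance on raw
sequencing counts.

## Evaluation

`score_networks()` scores the common network against the intersection of
the two truth graphs and the differential network against their symmetric
difference, inside an explicit candidate universe. The universe is the
set of pairs the constraints actually allow (optionally restricted to
evaluated layers): pairs excluded by constraints are not counted as true
negatives, which would otherwise inflate specificity. Differential edges
are compared at the pair level by default — the condition label is
ignored, matching how the differential F1 is defined in the simulation
study — with a strict label-matching mode available. `pauc()` integrates
the ROC curve by trapezoids over FPR $\in [0, 0.1]$ by default and
normalizes by the cutoff (perfect classifier 1, random classifier
cutoff/2); the cutoff is configurable since figure conventions vary.
`sweep_lambdas()` reproduces the per-$\lambda_1$ best-$\lambda_2$
protocol, breaking F1 ties toward larger $\lambda_2$. The default grid
factorizes the 640-combination budget as 32 log-spaced $\lambda_1 \in
[0.02, 1]$ times 20 log-spaced $\lambda_2 \in [0.001, 0.5]$; the tests
and the acceptance script use an 8×6 sub-grid of the same ranges to keep
replicate sweeps fast at their problem sizes (60 nodes, 10 replicate
seeds).

## Hyperparameter tuning

`run_cv()` performs repeated 5-fold cross-validation (10 repeats by
default; folds drawn per condition so both conditions contribute to every
split). For each fold and penalty pair the model is fitted on the
training split, each node's selected predictor set is binarized, and
plain least squares is re-estimated on that support — removing the
shrinkage bias of $\lambda_1$ — before predicting the held-out samples.
The criterion is the relative reconstruction error
$\operatorname{var}(x_{est} - x_{truth}) / \operatorname{var}(x_{truth})$,
averaged over nodes, conditions, folds, then repeats (in that order). A
node with empty support predicts 0, so the empty model scores exactly 1
on standardized data, a useful calibration point.

Design choices where the procedure was genuinely open:

* **No leakage:** test folds are standardized with the training fold's
  centers and scales.
* **1-SE rule:** among pairs whose error is within one standard error of
  the minimum *and* componentwise no less penalized than the minimizer,
  the largest $\lambda_1$ then the largest $\lambda_2$ is chosen —
  $\lambda_1$ first because it controls overall sparsity and is the
  parameter the rule is typically applied to.
* **Sequential mode** scans $\lambda_1$ with $\lambda_2$ fixed at its
  grid minimum (least interference with the sparsity path), then scans
  $\lambda_2$ at the chosen $\lambda_1$.
* **Folds vs 80/20:** the 5-fold structure itself provides the 80/20
  train/test split; no separate independent split is drawn.

## Known limitations

* Exactly two conditions; more require refitting pairwise.
* Linear dependencies only, and no self-loops.
* Neighborhood selection recovers the edge pattern but not a full
  precision matrix; no graphical-Lasso-style joint estimate is produced.
* Differential-edge precision is sensitive to $\lambda_2$; at small
  $\lambda_2$ the differential network inherits the union of both
  conditions' sampling noise. Use `run_cv()` or domain knowledge rather
  than defaults.
* The closed-form update relies on the divisor-$N$ standardization; data
  standardized with the $N-1$ convention will be re-standardized rather
  than accepted as-is.
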