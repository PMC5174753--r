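---
title: "Cost-sensitive trees and the bootstrap reliability of their terminal nodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive trees and the bootstrap reliability of their terminal nodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A classification tree used as a clinical screening tool does two things at
each terminal node: it assigns a class ("with disease" / "without disease")
and it reports a probability supporting that class.  Both are estimates, and
trees are notoriously sensitive to small perturbations of the training data.
`leafboot` quantifies, node by node, how much either output can be trusted:
it refits the tree on bootstrap resamples of the training set and watches
how each original terminal node's predictions move.

The package has three layers, each usable alone:

* a **synthetic cohort generator** emulating a fatty-liver (NAFLD) screening
  population — 30 mixed-type risk factors with published group-conditional
  marginals and a planted, tree-shaped outcome mechanism;
* a **cost-sensitive, GUIDE-style classification tree**: unbiased
  split-variable selection through chi-squared tests, interaction-aware
  two-level split search, optional bivariate linear splits, and 10-fold
  cross-validated cost-complexity pruning;
* the **bootstrap reliability analysis** of the fitted tree's terminal
  nodes.

## The tree

### Costs and the classification threshold

Misclassification costs enter as class weights: rows of class 1 (diseased)
carry weight `cost_fn`, rows of class 0 weight `cost_fp`.  Every impurity,
error and label computation uses these weights, so a node with class-1
proportion $\hat p$ is labelled diseased exactly when $\hat p > k$ with

$$k = \frac{C_1}{C_1 + C_2}, \qquad C_1 = \texttt{cost\_fp},\; C_2 = \texttt{cost\_fn},$$

the expected-cost-minimising rule.  Equal costs give $k = 1/2$; the 1:2
setting used to make a screening tree more sensitive gives $k = 1/3$.  The
boundary $\hat p = k$ goes to class 0.  When costs are unequal the
literature sometimes describes the threshold loosely as a weighted average
of prior probabilities; we implement the expected-cost rule because it is
the unique rule consistent with the weights used during growth, and
`update_costs()` lets a user relabel a fitted tree under any other cost
pair.

### Unbiased split selection

Exhaustive-search trees are biased towards predictors with many distinct
values.  Following the GUIDE family, variable selection is separated from
cutoff search: at each node every predictor is reduced to at most four
categories (continuous variables are binned at the node-local quartiles,
boundary values falling in the lower bin; ordinal and nominal variables
keep their levels) and tested against the outcome with a Pearson
chi-squared test on the cost-weighted contingency table.  P-values are
Bonferroni-adjusted by the number of computable tests.  Pairs among the
`interaction_top_k` (default 5) strongest candidates additionally get an
interaction test: the outcome against the $2\times2$ cross-classification
of the coarsely binned pair (median cuts for numeric variables,
class-share grouping for nominal ones), adjusted by the number of pairs.
An interaction pair wins only when its adjusted p-value beats every main
effect.

Two defaults bound the screen: `interaction_top_k = 5` screens the 10
pairs of the strongest main-effect candidates rather than all
$\binom{30}{2}$ pairs, and `interaction_min_n = 50` skips pair tests at
nodes too small to support the $2\times2\times2$ interaction table (below
50 rows its cells average fewer than ~6 observations and the test is
noise).  Both retain the interactions that can actually win the selection
in data of this kind, and both are `tree_control()` knobs.

### Split search

* **Numeric / ordinal**: every midpoint between consecutive distinct sorted
  values is scanned; the split maximising the decrease in cost-weighted
  Gini impurity, subject to both children holding at least `min_leaf` rows,
  wins; ties keep the smallest cutoff.
* **Nominal**: levels are ordered by weighted class-1 share and the at most
  $L-1$ prefix subsets scanned (for two classes the optimal subset is
  always of this form).
* **Interaction pairs**: a two-level search — split the node on one member,
  each child optimally on the other, in both orientations; the orientation
  with the lower total impurity contributes its top-level rule, ties
  keeping the first member.  A pure interaction leaves the marginal
  impurity of the top variable flat, so when the marginal-best rule
  reduces impurity by less than 10% of the node's own, the node median is
  also evaluated as a top-level cutoff (listed first, so ties prefer the
  balanced cut); with a strong marginal the marginal-best cut is already
  the two-level answer.
* **Bivariate linear splits** $a x_i + x_j \le c$: searched only when no
  interaction test is significant (at `interaction_alpha = 0.05` after
  correction), only at nodes with at least `linear_min_n = 50` rows (an
  oblique boundary estimated from fewer points is noise), and only over
  the two continuous variables with the smallest
  curvature p-values.  The direction grid is 41 angles uniform in
  $(-\pi/2, \pi/2)$ on the standardised variables — the paper-style display
  normalises $x_j$'s coefficient to 1 — and each direction's cutoff is
  optimised like a univariate split.  A grid is used because the objective
  is piecewise constant in the direction; `linear_preference` rescales the
  linear split's impurity reduction when it competes with the best
  univariate split.

Growth stops at pure nodes, nodes smaller than `min_split` (default 5),
depth `max_depth` (default 30, which also keeps the $2t/2t+1$ node ids in
integer range), or when no feasible split exists.  If the selected variable
admits no feasible split the next-best variable is tried, so nodes are not
terminalised prematurely.  All tie-breaks (column order, smallest cutoff,
first subset, first angle) are deterministic, making runs exactly
reproducible.

### Pruning

The fully grown tree is pruned by cost-complexity: the weakest-link
sequence is computed with node risk = cost-weighted misclassification, and
10-fold cross-validation (folds stratified by outcome; each fold's tree
regrown with identical settings) estimates the held-out cost of each
complexity value.  The default picks the minimum-CV-cost subtree (ties →
smaller tree), because the method's description asks for the smallest
cross-validated error rate; a one-standard-error rule is available via
`rule = "1se"`.

## The reliability analysis

Let $T$ be the pruned tree and route the held-out test set through it.  For
each terminal node $t$: $n_t$ test rows, observed diseased fraction
$\hat P(t)$, and reference class $\hat c(t) = \mathbf 1\{\hat P(t) > k\}$
(`class_source = "train"` instead takes the fitted tree's label).  Then for
$b = 1, \dots, B$ (default 500) the training set is resampled with
replacement (resamples missing a class are redrawn and counted), a tree
$T_b$ is grown and pruned with identical settings, and

$$\hat p_b(t) = \text{fraction of the test rows of node } t \text{ that } T_b \text{ predicts diseased}.$$

From the replicate matrix:

* **Refined probability** $\hat P_B(t) = B^{-1}\sum_b \hat p_b(t)$.
* **Classification reliability**
  $R_c(t) = 100\,B^{-1}\sum_b c_b(t)$, where $c_b(t)$ indicates
  $\hat p_b(t) > k$ for a class-1 node and $\hat p_b(t) \le k$ for a
  class-0 node (the same strict/weak boundary convention as the label
  rule).  A node is flagged when $R_c(t) \le 100k'$, default $k' = 0.95$.
* **Variance decomposition.**  The variance of the bootstrap standard
  error of a binomial proportion at $(\hat P_B, n_t)$ splits into a
  sampling and a resampling component.  Substituting the exact binomial
  moments $\mu_2 = npq$ and $\mu_4 = npq(1 + 3pq(n-2))$ into the
  kurtosis expansion collapses the sampling component to the closed form

  $$V_I = \frac{2\hat P_B \hat Q_B (n_t - 3) + 1}{4 n_t^2},$$

  (using $\mu_4/\mu_2 - \mu_2 = 1 + 2pq(n-3)$, an identity the test suite
  checks numerically), and the resampling component to $V_{II} = V_I / B$,
  which at $B = 500$ is under 0.2% of the total — the basis for treating
  resampling error as negligible at that $B$.  Printed renderings of this
  decomposition elsewhere are typographically ambiguous; the algebraic
  substitution fixes both components unambiguously and is what we
  implement.
* **Worst-case reference.**  $\hat P_B$ is shrunk towards $1/2$ on the
  logit scale, $p' = \text{expit}(\varepsilon\,\text{logit}(\hat P_B))$
  with $\varepsilon = 10^{-4}$, and $V_R$ is the $V_I$ formula evaluated at
  $p'$ — essentially the maximum variance attainable at that $n_t$.
  Probabilities are clamped to $[10^{-6}, 1-10^{-6}]$ before the logit
  (undefined at 0 and 1); at $\varepsilon = 10^{-4}$ the clamp moves $p'$
  by less than $10^{-3}$.  Shrinking the mean rather than averaging shrunk
  replicates is a choice; the two agree to $O(\varepsilon^2)$.
* **Prediction reliability** $R_P(t) = 100\,V_I / V_R$.  Values near 100%
  mean the node's probability is about as unstable as it could be; nodes
  with $R_P > 100k'$ are flagged.  The ratio uses the sampling component
  alone, which reproduces the exact 100% of the canonical three-row worked
  example; `include_resampling = TRUE` uses $V = V_I + V_{II}$ instead
  (multiplying every ratio by $1 + 1/B$).

Degenerate sizes: at $n_t = 3$ the $(n-3)$ term vanishes and
$V_I = V_R = 1/36$ for every probability, so $R_P \equiv 100\%$ —
three-row nodes are always prediction-unreliable, which is the sensible
verdict.  For $0 < n_t < 3$ the formulas stay non-negative but $V_R$ can
reach 0, so $R_P$ is reported missing and the node flagged `tiny_node`;
$n_t = 0$ nodes are flagged `no_test_data`.

## The synthetic cohort

No subject-level data is distributed with studies of this kind, so the
generator builds cohorts with the published structure: a latent outcome
group (prevalence 359/1600 ≈ 0.224), predictors drawn from their
group-conditional marginals — category probabilities for the 18 nominal
variables and the 4-level ordinal BMI, truncated normals (lower bound 0)
for the 11 continuous measurements, with the location parameter solved so
the *truncated* mean equals the published mean — and an observed outcome
drawn from first-match planted rules:

| stratum | risk |
|---|---|
| BMI ∈ {UW, N} | 0.05 |
| WHR > 0.9 and ALT > 17.5 | 0.80 |
| TG > 247.5 | 0.60 |
| otherwise | 0.336 |

The first three rules mirror the splits reported for the real cohort; the
residual risk 0.336 is calibrated once, analytically (the rule strata are
functions of the predictors alone, so implied prevalence is linear in the
residual risk), to make the implied prevalence equal 359/1600.  BMI is
generated as an ordinal variable because the published trees split it
categorically; the split search respects its order.  The train/test split
is stratified by outcome by default — the original 70/30 split's design is
not stated, and stratification stabilises small-node counts;
`stratify = FALSE` gives the simple random split.  A single integer seed
drives everything; the pipeline derives stage seeds as fixed offsets
(generation `seed`, split `seed+1`, pruning `seed+2`, bootstrap `seed+3`),
and all bootstrap randomness runs in one stream so reruns are
byte-identical.

What the generator does *not* emulate: within-group predictor–predictor
correlation (predictors are conditionally independent given the latent
group), measurement error, missing values, or the sonography-based label
process.  Passing tests on these cohorts therefore demonstrate that the
algorithms do what they claim under a known mechanism — parameter recovery,
cost monotonicity, reliability flags concentrating in small or
threshold-near nodes — not that the original study's specific trees or
reliability percentages would be reproduced on its (unavailable) data.

## Problem sizes used by the test suite

The suite exercises the full study geometry — cohorts of 1600 split
1120/480 — with $B = 200$ bootstrap replicates over 20 seeds for the
reliability behaviour checks and $B = 500$ in the acceptance script, the
value at which the resampling share of the variance drops below 0.2%.
Oracle comparisons (exhaustive split enumeration, exact binomial moments)
run at small $n$ where enumeration is exact.

## Known limitations

* Missing values are rejected, not surrogate-split.
* The response must be binary; ordinal severity grades are out of scope.
* The split-selection tests are a GUIDE-*style* approximation (quartile
  binning, Bonferroni-corrected pair screen), not a re-implementation of
  the original program; agreement with it is bit-exact in spirit, not in
  splits.
* Reliability is assessed for terminal nodes only, by the variance-ratio
  method; jackknife and standard-error-based variants are not implemented.
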