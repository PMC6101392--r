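---
title: "Sparse linear SVMs, variable-step elimination and value-resampling: the methods behind vssrfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse linear SVMs, variable-step elimination and value-resampling: the methods behind vssrfe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vssrfe)
```

## The problem

Two-class expression matrices — a few dozen samples, thousands to tens of
thousands of genes, and usually more samples in one class than the other —
pose two coupled problems: finding the small subset of genes that carries
the class signal, and judging that subset by how well a classifier built on
it generalises. Backward elimination with a linear SVM (SVM-RFE) is a
standard answer to the first problem, but refitting an SVM once per
discarded gene is expensive at microarray dimensionality, and class
imbalance biases both the gene ranking and the headline accuracy. This
package combines three pieces that attack cost and imbalance together,
plus the harness (standardization, stratified cross-validation, metrics,
synthetic data) needed to use and test them.

## Random value-based oversampling (RVOS)

`rvos_balance()` equalises class counts by synthesising minority-class
samples. Each synthetic sample is assembled gene by gene: the value for
gene *j* is drawn uniformly, with replacement, from the *observed* values
of gene *j* among the minority samples. Under the working assumption that
same-class samples share a distribution, the synthetic sample is a new
draw from the product of the per-gene empirical marginals.

Two properties follow and are enforced by tests: every synthetic value is
a real measured value (no interpolation, unlike SMOTE — expression values
are biological measurements and arithmetic blends of them are not), and
the per-column empirical distribution of a large synthetic batch converges
to the uniform distribution over the observed values. The price is that
gene–gene correlation within a synthetic sample is destroyed; RVOS
preserves marginals, not joint structure. With very small minority classes
the scheme is also limited by its finite value pool: duplicated synthetic
rows are possible and permitted (they are flagged by a `.syn` suffix in
`.sample_id`).

Sampling is with replacement within a column because the number of needed
samples can exceed the minority count. Balancing happens before
standardization in the bundled pipeline, so the standardizer sees the
class-balanced value distribution; the order can be changed by composing
the verbs differently.

## The sparse linear SVM (LLSVM)

`llsvm()` trains the L1-regularized squared-hinge linear classifier

$$\min_w \; \|w\|_1 + C \sum_{i \in I(w)} b_i(w)^2, \qquad
b_i(w) = 1 - y_i w^\top x_i, \qquad
I(w) = \{ i : b_i(w) > 0 \},$$

with labels $y_i \in \{-1, +1\}$ and the decision rule
$\hat y = \mathrm{sign}(w \cdot x)$. The L1 penalty sends the weights of
uninformative genes exactly to zero, which is what makes the per-gene
|weight| a usable importance score; $C > 0$ trades loss against sparsity
(as $C \to 0$ every weight collapses to zero).

Training is cyclic coordinate descent. For coordinate $j$ the smooth part
of the objective has one-sided derivatives at the current point,

$$d_1 = -2C \sum_{i \in I(w)} y_i x_{ij} b_i(w), \qquad
d_2 = \max\Bigl(2C \sum_{i \in I(w)} x_{ij}^2,\; 10^{-12}\Bigr),$$

and the one-variable model $|w_j + z| + d_1 z + \tfrac{d_2}{2} z^2$ has a
closed-form minimiser (`solve_subproblem()`): a Newton-like step shrunk by
the penalty, or a snap of the coordinate to exactly zero when the
subgradient interval at zero contains the slope. The $10^{-12}$ floor
keeps the step defined when the active set is empty.

Because the squared hinge is not twice differentiable, the quadratic model
can overshoot. Each step is therefore safeguarded by Armijo backtracking
on the *true* objective (accept $\beta^t z^\*$, $\beta = 0.5$,
$\sigma = 0.01$, $t \le 30$, at the first sufficient decrease), which
guarantees a monotonically non-increasing per-sweep objective trace — an
invariant the test suite asserts on randomized instances, alongside a
subdifferential optimality certificate at convergence and agreement with a
dense grid-search oracle on tiny convex instances.

Numerical choices worth knowing:

* **Stopping**: a sweep whose largest accepted step is below `tol`
  (default `1e-6`) ends the fit; `max_sweeps` (default 1000) bounds it.
* **Margins** $b_i$ are cached and updated incrementally after each
  accepted step ($O(n_{\text{samples}})$ per coordinate) and recomputed in
  full every 50 sweeps to bound floating-point drift.
* **Coordinate order** is fixed ascending, for bit-level reproducibility.
* **No intercept**: the decision rule is bias-free; per-gene
  standardization centres the data instead. A constant column can be
  appended by the caller if an intercept is wanted.
* **Ties**: a decision score of exactly 0 predicts the +1 (majority)
  side — a measure-zero convention.
* The inner loop is compiled (Rcpp); the R-level `llsvm_objective()`,
  `llsvm_derivatives()` and `solve_subproblem()` expose the same
  quantities for inspection and testing.

## Variable-step-size recursive feature elimination (VSSRFE)

`vssrfe_select()` runs backward elimination: fit the estimator on the
surviving genes, rank by |weight| descending, delete the bottom of the
list, repeat until `n_selected` remain. Classic RFE deletes one gene per
iteration; at $p \approx 20{,}000$ that is $p - k$ fits. VSSRFE starts
with a large step `s_initial` and halves it (integer floor) whenever the
surviving gene count has halved, reaching steps of 1 for the final,
careful eliminations. The premise: in expression data only a few genes
relate to the labels, so early mass deletions discard genes that would be
ranked last anyway, while the end-game — where mistakes are costly — is
as fine-grained as classic RFE. From 2000 genes down to 4 with
`s_initial = 100` this takes 85 fits instead of 1996.

The schedule is implemented with three deliberate regularisations, chosen
because the natural loop ("halve when the count reaches exactly half")
is not well defined for arbitrary integer steps:

* the halving triggers on *count ≤ half of the reference*, applied
  repeatedly until it fails, so no halving point can be skipped;
* one deletion count per iteration — compute
  `min(step, remaining − n_selected)`, delete, then update the step — so
  the bookkeeping can never desynchronise from the true gene count;
* the clamp guarantees termination with exactly `n_selected` genes for
  every `(n_total, n_selected, s_initial)`, which a property test checks
  over 10,000 random triples.

Rank bookkeeping: survivors take ranks 1..`n_selected` by final |weight|;
eliminated genes follow in reverse elimination order (later deletion =
more important), batch-mates ordered by |weight| within the batch. Ties in
|weight| — frequent, since the L1 estimator produces many exact zeros —
are broken by original column position, with the later column deleted
first; this makes runs platform-independent. The estimator is refit from
scratch each iteration (a warm start is available but off by default, so
each ranking is an independent fit), and standardization happens once
before the loop rather than per iteration.

`vssrfe_select()` is generic over any estimator obeying the contract
"matrix + labels in, one finite weight per column out";
`llsvm_estimator()` and the e1071-backed `svm_estimator()` are bundled.

## Evaluation protocol

`stratified_folds()` shuffles within class and deals round-robin, so every
fold's class counts are within one sample of exact proportionality —
train/test class proportions stay equal, which matters when accuracy on
imbalanced data can be inflated by majority voting. The default is 5
folds, the domain's standard. `cross_validate()` hands each pipeline only
its training rows, so any preprocessing done inside the pipeline
(balancing, standardization, selection) is leakage-free by construction; a
test with an instrumented pipeline verifies held-out rows never reach
`fit`. Fold metrics are averaged unweighted.

Metrics are the field's standard trio plus rates: accuracy; the Matthews
correlation coefficient with the standard numerator
$TP \cdot TN - FP \cdot FN$ (zero returned when a denominator factor
vanishes, where the coefficient is undefined); and the Mann–Whitney AUC —
the probability a random positive outscores a random negative, tied pairs
counted ½ — which equals the trapezoidal ROC area. The positive class
defaults to the minority class; no convention is universal here, so the
choice is explicit and overridable. `grid_search()` selects parameters by
mean cross-validated accuracy, ties resolved toward the earlier grid
point.

## The synthetic generator, and what passing tests do not show

`simulate_expression()` draws noise genes from
$\mathcal N(0, \sigma^2)$ in both classes and shifts informative genes by
$\pm \text{effect}/2$ per class; defaults are 10 informative genes, effect
2, unit noise — a per-gene signal strong enough that the linear
separability assumed by the methods holds by construction in the
overparameterized regime. `benchmark_shapes()` provides the six canonical
benchmark dataset shapes (22/40×2000 up to 46/51×24481) so shape
statistics and balancing behaviour can be exercised at realistic
dimensions.

The generator makes genes independent: no gene–gene correlation, batch
effects, probe-level artifacts or heavy tails. Tests passing on this data
therefore certify algorithmic correctness (schedules, optimality,
invariants, leakage-freedom), not biological performance. One honest
consequence, measured rather than hidden: with 10 equally informative,
mutually redundant planted genes (1000 genes, 30+30 samples, effect 2,
`C = 0.5`, `s_initial = 100`), LLSVM-VSSRFE recovers about 7 of the 10 in
its top 10, stably across seeds — once a few of the redundant genes
separate the classes, the L1 penalty zeroes the rest, and they are
eliminated early. An independent L1 squared-hinge implementation behaves
identically under the same schedule, so this is a property of
L1-regularized RFE on redundant signals, not of this implementation.
Selecting slightly more genes than the planted count, or a milder penalty,
recovers more.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on simulated data:
schedule properties at up to 3000 genes, solver oracles on instances of at
most 5 samples × 3 genes (where dense grid search is a sound oracle by
convexity), balancing at the six benchmark shapes, and selection recovery
at 1000 genes × 60 samples over 5 seeds. These sizes exercise every code
path at a scale a laptop reruns in about two minutes.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_expression(22, 40, 2000, n_informative = 10, effect = 2,
                           seed = 1)
dataset_summary(sim$data)              # SDR 3.1%, IR 1.82

bal <- rvos_balance(sim$data, seed = 1)
std <- fit_standardizer(bal)
z <- apply_standardizer(bal, std)

tr <- vssrfe_select(z, n_selected = 10, s_initial = 100,
                    estimator = llsvm_estimator(C = 0.5))
glance(tr)                             # 79 fits instead of 1990
head(tidy(tr), 10)

cv <- cross_validate(z[c(tr$selected, "label")], llsvm_pipeline(C = 1),
                     k = 5, seed = 1)
glance(cv)
```

## Known limitations

* Binary labels only; multi-class data is rejected at load.
* No intercept in the linear model (by design; see above).
* RVOS ignores gene–gene correlation, and with a very small minority
  class its finite value pool limits sample diversity.
* `s_initial` is dataset-dependent and must be tuned (larger for higher
  gene counts); the package exposes it rather than guessing.
* Dense ARFF and delimited text are read natively; MATLAB containers must
  be converted to CSV first.
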