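---
title: "Methods: stacked neural-network QSAR for PAMPA permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked neural-network QSAR for PAMPA permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

permstack models the effective membrane permeability coefficient of small
molecules, logPe = log10(Pe in cm/s), measured by the parallel artificial
membrane permeability assay (PAMPA) at pH 7.4. This vignette is the
package's account of the science inside it: the measurement model, the
learning pipeline, the choices that were genuinely open, and what the
synthetic test bed does and does not establish.

## 1. From plate measurements to logPe

A PAMPA well is a donor compartment (volume $V_D$, initial concentration
$C_D(0)$) separated from an acceptor compartment ($V_A$) by a lipid-infused
membrane of area $A$ and apparent porosity $\varepsilon_a$. After an
incubation of $t$ seconds (minus a lag time $\tau_{ss}$), concentrations
$C_A(t)$ and $C_D(t)$ are read and converted to the effective permeability

$$P_e = -\frac{2.303\,V_D}{A\,(t-\tau_{ss})\,\varepsilon_a}\cdot
  \frac{1}{1+r_v}\cdot
  \log_{10}\!\left[1-\frac{1+r_v^{-1}}{1-R_M}\cdot
  \frac{C_A(t)}{C_D(0)}\right],
  \qquad r_v = V_D/V_A,$$

with the membrane retention $R_M$ inferred from donor/acceptor mass
accounting. Two retention conventions circulate, differing in the sign of
the acceptor term:

* `"printed"` (default): $R_M = 1 - \bigl(C_D(t)/C_D(0) -
  V_A C_A(t)/(V_D C_D(0))\bigr)$
* `"mass_balance"`: $R_M = 1 - C_D(t)/C_D(0) - V_A C_A(t)/(V_D C_D(0))$,
  the form a strict mass balance gives.

`membrane_retention()` implements both behind an explicit `form` argument
and does not adjudicate between them; all downstream defaults use the
printed form. Units are fixed at cm, s, cm³; concentrations enter only as
ratios, so any single consistent unit works.

Degenerate wells are signalled, not silently propagated: $C_A(t)=0$ means
$P_e = 0$ exactly and logPe is undefined (`no_permeation`); $R_M \ge 1$ is
`invalid_retention`; an inner bracket outside $(0,1)$ (transport too fast
for the incubation, or inconsistent concentrations) is `out_of_validity`.
`pampa_evaluate()` carries these as a status column so result tables stay
finite.

The classification boundary is logPe $\ge -6.2$ → "higher" permeability,
boundary inclusive. The cutoff is a convention tied to this experimental
setup at pH 7.4, exposed as an argument everywhere it is used.

`generate_pampa_measurements()` inverts the equation: given target logPe
values, a retention and instrument settings, it solves for $C_A(t)$ and
$C_D(t)$ so that the forward conversion reproduces the request to machine
precision (the round trip is tested at 1e−9). Requests whose inner bracket
falls below `min_bracket` (default 1e−9) are rejected: at that point the
compound has effectively equilibrated within the incubation and the
measurement carries no information about $P_e$ — e.g. logPe = −3 with a
4-hour incubation on the default instrument.

## 2. Descriptors and screening

`compute_descriptors()` produces a numeric table from SMILES through the
ChemmineR/ChemmineOB (OpenBabel) backend: physicochemical properties
(molecular weight, logP, molar refractivity, topological polar surface
area, hydrogen-bond donor and acceptor counts), functional-group counts
(including the acid count `nAcid`), element counts, ring and bond counts,
and the TPSA/MW ratio `tpsaEfficiency`. This is a deliberately compact,
fully topological/constitutional set: the backend computes no 3D geometry,
so no conformer generation is needed and CPSA-family surface descriptors
are out of scope. Descriptor *semantics*, not any particular engine's
catalogue, are what the method needs; the pipeline treats the descriptor
table as opaque numbers from here on, and any external descriptor table
with a `molecule_id` column flows through unchanged.

Screening is minimal and mechanical: `drop_nonfinite_columns()` removes
whole columns containing any non-finite value (keeping the matrix dense
with the simplest defensible policy), `drop_zero_variance()` removes
constant columns, and `correlation_screen()` *reports* pairs with
|r| > 0.8 without removing anything — redundancy is resolved by feature
elimination, which can judge it against predictive value, not by a blind
cutoff.

Scaling is min-max to [0, 1], fit on the training partition only and
reused verbatim for test, external and future data. Out-of-range values on
new data are intentionally **not clipped**: a molecule outside the training
descriptor ranges should look unusual to the networks, and clipping would
hide exactly the signal the applicability domain feeds on. Constant
columns map to 0.

## 3. Data partitioning

`split_dataset()` draws a seeded uniformly random three-way split with
explicit counts, defaulting to 16 external and 33 test molecules — on a
190-molecule table that is 141/33/16. Counts are explicit rather than
percentages because 80% of 174 is 139.2: no rounding rule reproduces a
141/33 split from a percentage, so the split takes the sizes directly.

## 4. Feature selection

`rfe_random_forest()` is backwards elimination wrapped in repeated k-fold
cross-validation (default 20-fold × 3 repeats). Inside every resample a
random forest (500 trees by default, `randomForest` engine) is fit on the
analysis rows only and ranks descriptors by impurity importance
(permutation importance is available); for each candidate subset size a
fresh forest on the top-ranked subset is scored by RMSE on the held-out
fold. Per-size RMSE is averaged over all folds and repeats and the
smallest size among the minima wins (parsimony tie-break). The candidate
grid defaults to a doubling sequence completed by the full size, since a
finer grid mostly re-measures noise at this sample size.

Because the ranking is recomputed inside each resample, information from a
validation fold can never influence the subset evaluated on it. The test
suite asserts this with a leak canary: a descriptor equal to the response
on the rows of one validation fold (noise elsewhere) must not improve the
cross-validated RMSE.

The selected subset is written as a plain-text manifest (one name per
line) so a known-good subset can be pinned and re-selection bypassed.

## 5. Networks, Rprop+, stacking

`mlp_init()` builds a feedforward perceptron with logistic hidden layers
and a single **linear** output neuron; weights start from a seeded standard
normal. The linear output is a deliberate choice for regression: a
logistic output cannot reach the boundaries of the scaled target range
without saturating gradients.

`train_rprop()` is full-batch Rprop+ with weight backtracking. Per weight:
on a consistent gradient sign the step grows by $\eta^+$; on a sign flip
the previous update is reverted, the step shrinks by $\eta^-$, and the
stored gradient is zeroed so the next iteration re-probes; steps stay
clamped to $[\Delta_{\min}, \Delta_{\max}]$. Constants are the canonical
ones: $\eta^+ = 1.2$, $\eta^- = 0.5$, $\Delta_0 = 0.1$,
$\Delta_{\min} = 10^{-6}$, $\Delta_{\max} = 50$. Training stops when the
largest absolute partial derivative of $E = \tfrac12\sum(o-y)^2$ falls
below `threshold` (default 0.01) or at `max_steps`. The ½ factor is kept
so reported errors match the standard convention of this algorithm family.
There is no regularisation, minibatching or early stopping: the datasets
are tiny, full-batch gradients are exact, and the protocol interrogates
overfitting explicitly instead of preventing it.

The gradient is exact backpropagation, verified against central finite
differences (1e−6 relative) on randomized architectures, and on convex
problems (a single linear neuron) training reaches the normal-equations
optimum within 1e−6.

`train_stacked_ensemble()` fits the base networks — defaults NN1 (20, 15,
5) and NN2 (30, 20, 10) — on the scaled training table, then trains a
(2, 1) meta network whose inputs are the base predictions and whose target
is the observed response. Both descriptors and the response are scaled to
[0, 1] from the training data; predictions are reported back in logPe
units. The default meta-feature mode is **resubstitution** (base
predictions on their own training molecules), matching the classical
stacked-regression recipe on a small dataset where base models are
deliberately overfit; `out_of_fold` (cross-validated meta features,
averaged over repeats) is offered as the statistically safer variant. A
network whose training produces a non-finite error is retried once with a
shifted seed and then fails loudly — folds are never silently skipped.

## 6. Evaluation semantics

All statistics distinguish three contexts. `cv`: the model is refit on
each analysis part of a repeated k-fold plan and scored on the held-out
fold, with every statistic averaged across all folds and repeats.
`resubstitution`: the trained model predicts its own training set — a
diagnostic of overfitting, not of predictive value. `holdout`: prediction
on untouched test/external partitions. Two R² conventions are computed
side by side because they answer different questions: the residual form
$1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$ (unbounded below, punishes
shifts) and the squared Pearson correlation (0–1, shift/scale invariant).

The ranking score is the gain-curve **relative Gini**: items are sorted by
decreasing prediction, the cumulative share of the outcome total traces a
curve, and the area between that curve and the diagonal is divided by the
same area under the ideal outcome-sorted curve. Two conventions had to be
fixed where the classical plotting recipe is silent. First, outcomes are
shifted by their minimum before accumulation — logPe is negative
throughout, and without the shift the "total outcome" would be negative
and the curve meaningless; a perfect sorter still scores exactly 1 by
construction. Second, tied predictions advance the curve as one pooled
segment, which equals the average over all orderings of the tied items, so
a constant predictor scores exactly 0. An exhaustive brute-force oracle
over all orderings for n ≤ 6 pins the implementation down.

The fold-level RMSE vectors of the two base models are kept so their
Pearson correlation can be reported: weakly correlated base errors are the
point of stacking. The correlation is computed on fold RMSEs (not pooled
predictions) because that is the resample-level quantity the plan makes
comparable across models.

## 7. Applicability domain

For each molecule the spread of the k base predictions,
$SD(j) = \sqrt{\sum_i (y_i - \bar y)^2/(k-1)}$, measures ensemble
disagreement in logPe units. The domain threshold is 3 × the maximum SD
observed on the training molecules; predictions above it are returned but
flagged. Every training molecule is inside by construction of the
maximum — the threshold is only informative for new data. With the default
two base networks the SD reduces to $|y_1 - y_2|/\sqrt2$, so the domain is
exactly "where the two architectures agree".

## 8. Baselines and interpretation

`fit_linear_baseline()` is ordinary least squares on a small descriptor
subset, evaluated under the identical CV plan and holdout protocol as the
networks — the yardstick that quantifies what the nonlinearity buys.
`surrogate_tree()` fits a single CART regression tree (`rpart`) on centred
and scaled descriptors over the whole dataset and reports per-leaf mean
logPe, counts, percentages and the higher/lower class of each leaf at the
cutoff; its default complexity settings aim at a readable tree (about a
dozen leaves on ~200 molecules), not at maximal fit.

## 9. The synthetic test bed

`generate_descriptor_dataset()` emulates the *structure* of a curated
PAMPA QSAR table so every pipeline stage is testable without any download:

* 190 molecules × 100 descriptors by default, standard-normal noise
  columns;
* 5 informative descriptors driving the response through a linear part,
  one pairwise interaction and one saturating `tanh` — rich enough that a
  nonlinear stack can beat the linear baseline, with every informative
  column findable by a forest;
* one 10-column block sharing a latent factor (pairwise r ≈ 0.9),
  emulating the strong descriptor redundancy of real tables;
* 5 all-zero columns emulating never-triggered descriptors;
* response centred at −6.2 with spread 0.9, spanning roughly −8.5…−4.5 so
  the two permeability classes are roughly balanced;
* Gaussian response noise with SD 0.2 log units — the order of PAMPA
  inter-replicate reproducibility.

The ground-truth record keeps the informative/constant/block names, the
noise draws and the noise-free signal (the best possible prediction), so
tests can check *recovery* (selection finds the planted names; no model
beats the Bayes predictor beyond sampling tolerance) rather than just
smoke. `add_output_noise()` perturbs the response with seeded Gaussian
noise for robustness studies.

What the synthetic bed does **not** establish: real descriptor tables have
skewed, discrete and heavy-tailed columns, correlated noise, and an
unknown, certainly non-additive true signal; synthetic molecules are
descriptor vectors with opaque ids, not chemistry. Green tests show the
machinery is correct and the protocol behaves as designed — they do not
certify predictive accuracy on laboratory data.

## 10. Problem sizes, tolerances, degenerate inputs

The test suite and protocol checks run at deliberately desk-scale sizes:
190 × 100 for full-protocol runs (4000 Rprop+ steps per network), 80–150
molecules and 8–40 descriptors for selection and stacking properties, 20
seeded repetitions for the stacking-dominance check, 5-fold single-repeat
CV where the full 20 × 3 plan adds nothing to the property under test.
These sizes were chosen so the complete suite exercises every code path in
about a minute while keeping each statistical assertion comfortably away
from its noise floor.

Numerical conventions worth knowing: exact-arithmetic identities are
asserted exactly (rational inputs), analytic-vs-finite-difference
gradients at 1e−6 relative, PAMPA round trips at 1e−9, algebraic metric
identities at 1e−12. Degenerate inputs fail loudly with typed conditions
(`permstack_value_error`, `permstack_io_error`, `permstack_numeric_error`):
constant responses, constant prediction vectors (Pearson undefined),
empty batches, k < 2 ensemble members, rank-deficient linear designs.
Model persistence writes every weight with 17 significant digits, which
round-trips IEEE doubles exactly; a save/load/predict cycle is bit-identical.

## 11. Known limitations

* The descriptor backend is topological/constitutional only; models built
  on it are not comparable descriptor-for-descriptor with CDK- or
  RDKit-derived tables, and geometry-sensitive chemistry (conformational
  polarity, intramolecular hydrogen bonding) is invisible to it.
* The default resubstitution stacking inherits the classical recipe's
  optimism: its cross-validated statistics on the meta level are not
  honest generalization estimates. Use `mode = "out_of_fold"` when that
  matters.
* The applicability domain sees only ensemble disagreement; a molecule on
  which both architectures are confidently wrong passes the gate.
* pH is not modelled: measurements and predictions are tied to the assay
  condition the training data were measured at (pH 7.4 for the intended
  use), and ionisable compounds can behave very differently elsewhere.
* No tautomer/protonation-state enumeration and no new descriptor
  definitions: the package models the table it is given.
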