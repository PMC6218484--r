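---
title: "Contextualizing probabilistic logic networks with mixed regularization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextualizing probabilistic logic networks with mixed regularization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbnlogic)
```

## The model

`dbnlogic` fits probabilistic logic networks — quantitative generalizations
of Boolean signalling models, often called Dynamic Bayesian Networks in this
literature — to steady-state protein measurements from one or more cellular
contexts (cell lines). Each node carries an activity in [0, 1] representing
the relative abundance or activation of a signalling molecule. Signed,
gated interactions link the nodes, and each interaction carries one strength
parameter `k` in [0, 1] (minimal parametrization: one parameter per
interaction).

A node's update is

    a   = sum over activating interactions of k_i * g_i
    x'  = a * prod over inhibitory interactions of (1 - h_j * g_j)

clipped to [0, 1], where the gate value `g` is the source activity for a
single-source interaction, the product of source activities for an AND gate,
and the probabilistic union `1 - prod(1 - x)` for an OR gate. Inhibition is
multiplicative (the NOT operation), so a saturating inhibitor (`h = 1`,
source fully active) silences its target completely. With all parameters at
1 and binary inputs, an acyclic network reproduces classical Boolean
evaluation exactly; the test suite asserts this Boolean limit.

Activities are read at a deterministic fixed point: synchronous sweeps from
a fixed initial state (0 for every unclamped node) until the largest
per-node change falls below a tolerance (`dbn_sim_control()`, default 1e-6).
Input nodes are clamped to their experimental stimulation levels for all
sweeps, and constitutively active nodes are clamped to 1 unless overridden.
Synchronous updating makes the result independent of node ordering; the
update scheme is otherwise a free choice, since only fixed points are
interpreted. Feedback loops (for instance the NFkB–IkBa negative loop in
the packaged melanoma network) can oscillate under synchronous updates at
extreme parameter values; non-convergence is therefore reported through a
flag and the last state is used, never raised as an error — during
optimization such regions score badly and are left naturally.

## The objective

For measurements `X` (N data points over contexts, conditions and measured
nodes) and simulated counterparts `Xhat`, the fit minimizes, over all
parameters of all contexts jointly,

    (1/N) sum (X_i - Xhat_i)^2
      + lambda1 * sum over all parameter instances sqrt(k)
      + lambda2 * sum over reactions g, contexts j of | k_j^g - mean(k^g) |

subject to `k in [0,1]` and, for every node with two or more incoming
activating interactions, the constraint that those strengths sum to exactly
1 per context (activator competition). The three terms encode goodness of
fit, sparsity, and cross-context parsimony:

* **L1/2 semi-norm** (`sum sqrt(k)`, exponent q = 0.5). Under the
  sum-to-one constraint a plain L1 penalty is constant within each
  competition group, so it cannot prune; the fractional norm still rewards
  concentrating weight on few interactions. Reactions that are not needed to
  explain the data in any context are driven to 0.
* **Grouped L1 across contexts.** Each reaction's per-context values form
  one group; penalizing deviations from the group mean collapses reactions
  that do not genuinely differ between contexts onto a single shared value,
  so that context-specific parameters remain only where the data demand
  them. For a two-context group the penalty is exactly `|k_1 - k_2|`.

Both contexts are fitted in a single optimization with one N over the
pooled data points — the objective defines one MSE over the whole dataset,
not one per context. Measurement SEMs are carried through for plotting and
reporting but do not weight the MSE.

A deliberate modelling assumption, flagged prominently: **the sum-to-one
constraint applies only to nodes with two or more activators.** A single
activator keeps a free weight in [0, 1]. Constraining single activators
would pin every chain weight at exactly 1 and make whole cascades
non-identifiable, which cannot be intended.

## Optimization

`dbn_fit()` uses multi-start L-BFGS-B (default 10 starts for single fits, 3
inside grid scans) on box-constrained variables, with the competition
constraints enforced by a normalization reparametrization: the optimizer's
free variables are mapped onto the constraint surface by dividing each
competition group by its sum, per context, before every evaluation. The
constraint therefore holds exactly at every step rather than approximately
through a penalty. The non-smooth terms are smoothed only inside the
optimizer — `sqrt(k + eps)` and `sqrt((k - kbar)^2 + eps)` with
`eps = 1e-8` — and every reported value (MSE, penalties, objective) is
recomputed exactly. Gradients are central finite differences evaluated in
compiled code with a tightened fixed-point tolerance (1e-9), which keeps
the differentiation noise well below the step size. Starts are drawn
uniformly from the box under a recorded seed; identical seeds and settings
reproduce a fit bit-for-bit.

## Model selection

`make_grid()` builds the half-log axis `1e-10, 10^-9.5, ..., 1e2` — 25
nonzero values, 26 with the leading 0 — and `dbn_scan()` fits every
(lambda1, lambda2) combination, 676 models for the default axes. Cells are
warm-started from the previous solution along the path so that neighbouring
models stay similarly parametrized. Each cell is scored by
`BIC = N log(MSE) + log(N) P` with an *effective* parameter count P: at the
pruning threshold (0.01), a reaction below threshold in every context
contributes 0, a reaction whose context values agree within the threshold
contributes 1, and any other reaction contributes one parameter per
context. The minimum-BIC cell is selected; exact ties are broken toward the
more strongly regularized cell later in the scan order (parsimony). The
same thresholded classification labels every reaction of the selected model
as `inactive`, `shared`, or `context_specific`.

In-silico knockouts (`knockout_scan()`) remove one non-input node at a time
— activity clamped to 0, incident interactions deleted — refit per context
and time point, and report `delta AIC = AIC_KO - AIC_reference` with
`AIC = N log(MSE) + 2 P` and the reference scaled to 0. A positive delta
means the network cannot compensate for the node. Knockout refits are plain
MSE fits (lambda = 0) by default, configurable. The knocked-out node's
measurement rows are kept (its simulated activity is 0), so N is constant
and AICs are comparable across knockouts. A knockout that leaves no
measured node reachable from the clamped inputs is flagged
`disconnected = TRUE` and scored against the null model (no parameters, all
unclamped activities at rest) rather than left unscored — the information
that the network loses *all* explanatory power is exactly what the
bottleneck analysis needs.

## Interventions

Three idioms, applied to a fitted model (`predict_interventions()`):
`knockout` (clamp to 0, incident edges inert), `clamp` (hold at a fixed
activity), and `remove_incoming`, the super-repressor idiom: the node's
inhibitory (degradation) inputs are removed while its synthesis inputs are
kept — a non-degradable IkBa mutant continues to be produced but no longer
responds to IKK. A node left with no inputs at all is frozen at its basal
simulated activity, computed per context and condition from the unperturbed
model. Readout activities are reported raw in [0, 1]; an optional linear
calibration (`percent_scale()`) maps them to percent through user-supplied
anchor points and is never applied silently, because assay calibrations
(e.g. "an enrichment factor of 2 corresponds to 10% apoptosis" for
cell-death ELISAs) are assay-specific.

## Synthetic ground truth and what passing tests show

`generate_truth()` builds a random connected network with known parameters:
inputs first, every further node wired to an earlier node (so stimulation
reaches everything), extra edges — partly inhibitory — on top, parameters
drawn uniformly from [0.2, 0.9] and shared across contexts, then `n_zero`
reactions silenced in every context and `n_specific` reactions resampled
per context with a gap of at least 0.3. Competition groups are renormalized
afterwards. Two structural choices matter:

* Zero and context-specific labels are assigned only to parameters outside
  competition groups. Renormalizing a group after zeroing one member would
  silently change the partner's value and misclassify it, breaking the
  identity `effective count = (reactions - zero) + specific` that the
  generator guarantees by construction.
* Inactive reactions are drawn from inhibitory edges. Silencing an
  activation edge can cut off a subtree, turning downstream labels into
  questions the data cannot answer.
* By default every non-input node is measured (`measured_frac = 1`, with
  the 60%-of-nodes floor retained when lowered). Parameters of edges
  passing through unobserved nodes are structurally non-identifiable — only
  path products are — and a recovery benchmark is only meaningful against a
  recoverable truth. The packaged melanoma fixture, by contrast, keeps a
  realistic complement of unmeasured nodes.

`generate_data()` emits replicate-level values — steady state plus Gaussian
noise with per-replicate sd `noise_sem * sqrt(replicates)`, truncated at 0 —
mirroring a five-replicate quantitative immunoblot design with SEM error
bars on the normalized scale. `normalize_measurements()` applies the
min-max normalization used for such data: per protein, pooled over all
contexts, conditions and replicates, then replicate mean and SEM
(normalize-then-average; the reverse order is available via
`average_first = TRUE`). For parameter-recovery studies,
`generate_table()` skips the min-max step, since rescaling deliberately
destroys the very scale being recovered.

The generator emulates the *structure* of multi-context steady-state
protein data: two contexts, unstimulated/stimulated conditions, five
replicates, bounded normalized values, homoscedastic noise. It does not
emulate kinetics, densitometry saturation, correlated replicate errors,
batch effects, or time-resolved behaviour; passing recovery tests therefore
demonstrate correctness of the estimator under its own assumptions, not
performance on any particular laboratory dataset.

## The melanoma fixture

`melanoma_fixture()` ships a 19-node, 29-parameter network of
TRAIL-receptor-agonist signalling in melanoma: extrinsic apoptosis
(receptor → caspase-8 → caspase-3 → PARP), the mitochondrial amplification
loop with SMAC, NFkB survival signalling with the IkBa negative feedback,
and constitutive BRAF→MEK→ERK and PI3K→AKT growth signalling, with seven
measured proteins (AKT, ERK, FLIP, XIAP, IkBa, NFkB, PARP cleavage) and an
apoptosis readout. The three inhibitory reactions onto the cleaved caspases
(FLIP on caspase-8; BCL2 and XIAP on caspase-3) are as described for the
published model this topology reconstructs; the remaining edges follow the
canonical pathway chains and are tuned to the published node and parameter
counts, so individual edges beyond the named three are plausible rather
than authoritative. `melanoma_truth_params()` provides synthetic two-context
anchor parameters (19 shared, 4 inactive, 6 context-specific reactions; 31
effective parameters at the 0.01 threshold) encoding the resistance
phenotype — XIAP inhibition of caspase-3 near-absent in parental cells but
strong in conditioned cells — for demonstrations and tests. They are
labelled synthetic throughout: with only two stimulation conditions the
fixture's 58 free parameters are heavily under-determined, which is why
quantitative reproduction of the published fit requires the deposited
multi-timepoint dataset rather than the shipped template.

## Numerical choices and problem sizes

Defaults chosen once and used everywhere: simulation tolerance 1e-6 (1e-9
inside gradients), sweep budget `100 * n_nodes`, initial activity 0,
smoothing eps 1e-8, optimizer tolerance ~1e-9 on the objective
(`factr = 1e4`), pruning threshold 0.01, 10 restarts for single fits and 3
per scan cell with warm starts, uniform random starts. A zero MSE inside a
logarithmic criterion is floored at machine epsilon with a warning.
Degenerate competition groups (all members at 0 before normalization) fall
back to equal shares.

The shipped studies use sizes a desk-scale analysis can rerun end to end:
recovery studies use 12-node, 16-reaction truths (3 inactive, 3
context-specific, noise SEM 0.02, 5 replicates) over a reduced 7x7
regularization grid spanning 0 and 1e-4…10^-1.5 — the decade range where
the penalties are commensurate with the data term for data on this scale —
with 5 generator seeds. The full 26x26 default grid is exercised for its
structure (axis and cell counts) rather than refitted in every test run.

## Known limitations

Local multi-start optimization carries no global guarantee; with few
conditions, large networks are under-determined (the fixture illustrates
this deliberately); fixed points are the only dynamical object — no
trajectories, no dose–response kinetics; and the OR-gate algebra follows
the probabilistic-union convention, which may differ from other logic-model
toolboxes' weighted-sum conventions (a compatibility caveat when importing
topologies).
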