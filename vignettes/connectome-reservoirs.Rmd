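---
title: "Connectome-based reservoirs: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based reservoirs: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

Echo-state networks (ESNs) are recurrent networks whose internal weights
are fixed; only a linear readout is trained, in one shot, by ridge
regression. Conventionally the internal weight matrix is random. This
package asks what happens when it is *biological* instead: the signed,
weighted synaptic graph of the fruit-fly brain, carved down to a connected
reservoir of tractable size, drives the same leaky-tanh dynamics and is
compared against matched random controls on a chaotic forecasting task —
trajectories of the circularly-restricted three-body problem (CR3BP).

`connres` implements the full pipeline: table ingest and synapse quality
filtering, sign assignment from neurotransmitter predictions, two
connected-subgraph selection criteria, spectral rescaling, five reservoir
architectures, topology metrics, CR3BP generation, ESN training and
evaluation, and the Monte Carlo comparison grid with its statistics. A
synthetic connectome generator reproduces the statistical shape of the
real export so the whole pipeline is testable offline.

## From anatomy to a weight matrix

Synapse tables carry two quality scores and six neurotransmitter
probabilities per synapse. Synapses are kept when the cleft score is at
least 50 and the connection score at least 100 (equality retained — the
filter removes *below*-threshold rows), and when both endpoints are in the
classified neuron table. The predicted transmitter is the probability
argmax: GABA maps to a negative weight, acetylcholine and glutamate to
positive ones, and the three modulatory transmitters (octopamine,
serotonin, dopamine) are dropped, since a firing-rate model has no resting
potential for them to modulate. Exact argmax ties resolve by a fixed
priority order (GABA, ACh, Glu, Oct, Ser, Dop) purely for determinism.

The connection score serves as the weight magnitude. Two open points are
settled as follows and recorded in each graph's provenance:

* **Parallel synapses** between the same ordered pair are aggregated as
  the *signed sum* of their connection scores. This preserves total
  anatomical strength, lets opposed inputs cancel, and produces exact
  zero-sum edges, which are removed.
* **No normalization** is applied to raw scores: the later spectral
  rescaling makes any global scale irrelevant.

## Carving a connected reservoir

Both selection criteria demand a weakly connected subgraph of exactly N
neurons (a disconnected selection would be several independent smaller
reservoirs). "Degree" throughout is the count of distinct in- plus
out-edges after aggregation, and "connected" means weak connectivity of
the directed graph.

* **most-connected** ranks by degree, takes the top N, keeps the largest
  weakly connected component (size M ≤ N), and grows back to N by
  repeatedly adding the highest-degree *graph* neighbor of the component.
  (Neighbors are graph neighbors, not spatial ones — the goal of the step
  is connectivity.)
* **proportional** apportions N over the full-graph class proportions by
  largest remainder, takes each class quota's highest-degree members,
  joins the resulting components greedily — repeatedly connecting the two
  largest through the fewest-hop undirected path in the full graph and
  absorbing path interiors (M ≥ N) — then prunes lowest-degree nodes,
  skipping articulation points so connectivity survives, back to N.

The greedy join is deliberately not an exact Steiner tree (that problem is
NP-hard); the provenance of every selection records the criterion,
requested N, intermediate M and per-class quotas, so the approximation is
visible downstream.

The weight matrix entry `W[i, j]` is the aggregated signed weight j → i.
Before simulation every reservoir is rescaled to spectral radius 0.99 —
just inside the echo-state-property boundary, near the edge of chaos. The
spectral radius is computed densely up to order 300 and by
largest-magnitude Arnoldi iteration (ARPACK, four requested eigenvalues
for robustness against complex dominant pairs) above that, with a dense
fallback; the two paths agree to 1e-8 on seeded test matrices.

## Five architectures

Controls and hybrids isolate the contributions of topology versus weights.
All variants are rescaled to the same spectral radius, and within a
Monte Carlo cell all architectures share the trajectory, input map and
bias draws (matched pairs):

| kind | topology | weights |
|---|---|---|
| `control_random` | Bernoulli mask at the connectome's density | i.i.d. uniform(−1,1) or N(0,1) |
| `conn_topo_conn_weights` | connectome | connectome |
| `conn_topo_random_weights` | connectome | i.i.d. redrawn |
| `random_topo_conn_weights` | uniform mask with exactly the connectome's nonzero count | permutation of connectome weights |
| `conn_topo_shuffled_weights` | connectome | own weights permuted in place |

The exact-count random mask is drawn by sampling the required number of
entry positions without replacement — the distribution a
reject-until-match Bernoulli loop converges to, in one pass. The Bernoulli
control treats the diagonal like any other entry. Uniform(−1,1) and
standard normal are used for fresh weights; rescaling removes any global
scale, so only the shapes matter.

## The forecasting task

CR3BP trajectories are integrated in normalized rotating-frame units
(primary separation 1, angular rate 1) at the earth–moon mass ratio
μ = 0.0121505856, from the base initial state r = (−0.80, 0, 0),
v = (0, −0.63, 0.08), sampled every 0.1 time units for 10,000 points.
Integration uses adaptive lsoda at `rtol = atol = 1e-12`; the Jacobi
constant is evaluated at every sample and its drift recorded in the
trajectory's provenance (measured drift is ~2e-10 over the full length,
comfortably within the 1e-8 validity bound the tests assert; time-reversal
recovers the initial state to better than 1e-6). The trajectory family is
generated by multiplying each nonzero component of the initial state by
(1 + ε), ε uniform in ±1% — one independent draw per component per
trajectory.

Each trajectory splits into contiguous washout (500), training (6500) and
test (3000) windows; the split is configurable, since only the total of
10,000 points is fixed by the protocol. The washout erases the arbitrary
zero initial reservoir state (the fading-memory test verifies two runs
from different initial states collapse to within 1e-6 after 200 steps at
spectral radius 0.5).

## ESN equations and the readout

The state update is the leaky-tanh recurrence

    x[n] = (1 − α) x[n−1] + α tanh(W x[n−1] + Win [1; u[n]])

with α = 0.9 (one minus the 0.1 timestep) so 1 − α is the leakage rate.
Each input-receiving neuron is wired to exactly one of the three Cartesian
coordinates, chosen uniformly — so about a third of the neurons see each
coordinate — with input weight and bias uniform(−1,1) scaled by 0.7. The
inner loop is compiled (RcppArmadillo, sparse matrix-vector products), as
a 10,000-step run is the hot path of every trial.

Training is one-shot ridge regression, `Wout = Y Xᵀ (X Xᵀ + βI)⁻¹`.
Two regressor layouts exist. The default, `states_only`, regresses targets
on the visible reservoir states alone, which gives exactly 3 parameters
per visible neuron — 150 at N = 50, 4500 at N = 1500, matching the
protocol's parameter accounting. The alternative `full_regressor` stacks
`[1; x; u]`. The two are both implemented because the source formulation
is self-contradictory on this point; the default follows the parameter
count, which is checkable.

Forecasting is open-loop and direct: input u[n], target u[n+h] for horizon
h, trained and evaluated without feeding predictions back. The error
metric is

    nRMSE = RMS(all prediction errors) / mean_t ||y(t)||

i.e. root-mean-square error normalized by the time-mean Euclidean norm of
the target — non-negative, zero iff exact, invariant to common rescaling.
The printed source formula is dimensionally inconsistent as written
("squared norm" over "mean of Y"); this reading keeps the quantity a
genuine normalized RMS error, and the literal quotient stays available
behind `literal = TRUE`. On constant-norm targets with a constant offset d
on one coordinate the implementation reproduces the closed form
d/(c·sqrt(3)) exactly.

## Topology metrics

Degree, clustering and shortest-path distributions characterize selected
reservoirs. Directionality is handled explicitly:

* Degree distributions count distinct aggregated edges, separately for
  in, out, and total.
* The local clustering of node i uses its in-neighborhood or
  out-neighborhood (two declared variants); e_i counts unordered neighbor
  pairs joined by *at least one* directed edge, so C_i = 2e_i/(k_i(k_i−1))
  stays in [0, 1]. Counting both directions separately would allow
  C_i = 2, which no convention permits. Nodes with fewer than two
  neighbors get C_i = 0, keeping distributions count-conserving.
* Shortest paths are directed, unweighted hop counts over all ordered
  pairs; unreachable pairs are excluded from the histogram and counted
  separately.

Sparsity is the fraction of zero entries in the N×N matrix, and the
weight variance is the population variance over nonzero entries.

## The Monte Carlo grid and its statistics

`run_grid()` iterates criteria × sizes × spectral radii × distributions ×
trajectories × trials × architectures, and within a trial trains every
(β, horizon) readout from a single reservoir state run — states do not
depend on either parameter, so this is exactly the naive loop's result at
a fraction of the cost. The states-only Gram matrix is likewise cached per
horizon. Everything derives from one master seed; grids are reproducible
bit-for-bit.

Comparisons use:

* the **Mann–Whitney U test** (midrank ties, tie-corrected normal
  approximation, continuity correction), implemented in the package and
  cross-checked in tests against exact permutation enumeration and
  `stats::wilcox.test`; trials are pooled across the trajectory/trial
  cells of a combination. No multiple-testing correction is applied,
  matching per-marker reporting. Error bars are standard deviations of
  the mean.
* the **Bhattacharyya distance** over a shared-range 10-bin histogram of
  the two nRMSE samples, `DB = −ln Σ√(p_i q_i)`, averaged over sizes and
  regularizers. A datapoint-wise reading of the formula is not a
  distribution overlap, so the histogram construction is declared here
  and in the output.

Whole-connectome mode (`full_connectome_trial()`) restricts the input map
to sensory-class neurons and the readout to output-class neurons
(learning/hormonal readout classes), so the trainable count is three times
the output-class census; everything else is the standard pipeline.

## The synthetic connectome

The generator emulates what the analysis *assumes* of the real export:
the two-table schema; a class mix dominated by medulla classes (ME,
ME>LO first) including sensory and readout classes so class-restricted
modes are exercised; two mirrored spatial clusters; a directed rewired
ring lattice (default degree 8, rewiring 0.1) for high clustering plus
rank-preferential hub edges for heavy degree tails; connection scores
from shifted log-normals, one component per sign (excitatory fraction
0.6), giving the bimodal heavy-tailed signed weight distribution; and
tunable fractions of modulatory-argmax (5%) and sub-threshold (5%)
synapses so every filter branch fires. Scores sit entirely above the
quality thresholds except for the injected sub-threshold rows — a hard
floor would create a point mass that lets mixed-sign parallel synapses
cancel exactly, which the smooth shift avoids.

What it does **not** model: the real degree sequence, spatial wiring
statistics, class-conditional connectivity, or hemispheric asymmetries.
Consequently, passing tests demonstrate pipeline correctness and
protocol soundness — not that a synthetic reservoir reproduces the real
connectome's performance advantage. On synthetic graphs the
connectome-derived architectures hold no privileged position, and none is
asserted.

## Numerical choices and degenerate inputs

* Spectral rescaling requires a nonzero spectral radius; nilpotent or
  empty matrices raise an explanatory error rather than returning junk.
* Ridge training at β = 0 on singular systems raises an error advising
  β > 0; the states-only Gram solve is the standard `solve()` path.
* Probability vectors not summing to 1 are renormalized with a warning
  when the sum is within [0.5, 1.5] and rejected otherwise.
* Neuron identifiers are carried as character strings end to end: real
  exports use 64-bit ids that overflow R integers.
* Quota apportionment caps at class availability and redistributes the
  deficit by largest remainder, with a warning.
* Integration aborts with a named step when either massive primary is
  approached within 1e-6 (and a massless primary exerts no force, so the
  μ = 0 rotating-frame equilibrium is exact to 1e-10).

## Problem sizes used by the shipped checks

The test suite and acceptance script run entirely on generated data: the
reduced Monte Carlo grid uses a 2000-neuron synthetic connectome,
reservoir sizes {50, 200, 500}, β ∈ {1e-3, 1e-6, 1e-9}, horizons {1, 10},
five architectures, two trajectories × three trials under the
most-connected criterion — 540 evaluations, chosen as the smallest grid
that still exhibits the qualitative phenomenon of interest (the positive
overfitting gap of the control architecture at β = 1e-9) while exercising
every architecture path. Full-scale runs (sizes to 1500, four horizons,
five trajectories × ten trials, both criteria) use the same entry points
with the default `grid_spec()`.

## Known limitations

* The proportional criterion's greedy join can overshoot the minimal
  connector set; provenance records M so the overshoot is observable.
* The directed clustering convention is one of several in the literature;
  it is declared in `metric_report()` output rather than assumed
  universal.
* No autonomous closed-loop forecasting mode is provided; all evaluation
  is open-loop direct h-step prediction.
* Live database queries are out of scope; ingest is file-based, and the
  synthetic generator stands in for the real export's statistics, not its
  identity.
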