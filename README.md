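# connres

Reservoir computing with a brain instead of a random matrix.

Echo-state networks (ESNs) keep their recurrent weights fixed and train
only a linear readout, in one shot, by ridge regression:

```
x[n]  = (1 − α) x[n−1] + α tanh(W x[n−1] + Win [1; u[n]])
Wout  = Y Xᵀ (X Xᵀ + β I)⁻¹
nRMSE = RMS(Y − Ŷ) / mean_t ‖y(t)‖
```

Conventionally `W` is random. `connres` builds `W` from a fruit-fly
whole-brain connectome export instead — neuron and synapse tables in the
FlyWire/CAVE schema — and asks whether the biological topology and the
bimodal, heavy-tailed, signed synaptic weight distribution change how the
network forecasts a chaotic benchmark: trajectories of the
circularly-restricted three-body problem (CR3BP) in the rotating
earth–moon frame.

The package is aimed at computational-neuroscience and reservoir-computing
researchers who want the full pipeline as tested, reusable functions:

* **Ingest** (`read_tables`, `filter_synapses`, `assign_sign`,
  `build_graph`): synapse quality filter (cleft score ≥ 50, connection
  score ≥ 100, endpoints classified), sign from the neurotransmitter
  argmax (GABA −, ACh/Glu +, modulatory dropped), parallel synapses
  aggregated as signed sums.
* **Reservoir selection** (`select_most_connected`,
  `select_proportional`, `extract_weight_matrix`, `rescale_spectral`,
  `randomize`): two criteria for carving an exactly-N, weakly connected
  subgraph; spectral radius rescaled to 0.99; five matched architectures
  (control, full connectome, and the topology/weight hybrids).
* **Topology metrics** (`clustering_coefficients`,
  `shortest_path_distribution`, `degree_distribution`, `matrix_stats`,
  `metric_report`): directed small-world characterization.
* **Task** (`propagate`, `jacobi_constant`, `perturb_initial`,
  `split_trajectory`): CR3BP propagation at the earth–moon mass ratio,
  validated by Jacobi-constant drift below 1e-8 over 10,000 samples.
* **ESN core** (`build_input_map`, `run_reservoir`, `train_readout`,
  `nrmse`, `forecast_trial`): compiled reservoir loop, one-shot ridge
  readout, open-loop h-step forecasting.
* **Experiments** (`grid_spec`, `run_grid`, `summarize_grid`,
  `mann_whitney_u`, `bhattacharyya_distance`, `full_connectome_trial`):
  the Monte Carlo comparison grid with matched pairs, rank statistics
  and distribution overlaps, plus the whole-connectome mode whose input
  is restricted to sensory classes and readout to output classes.
* **Synthetic connectome** (`synth_config`, `generate_connectome`,
  `synthetic_graph`, `make_fixture`): a statistically matched generator
  (class mix, small-world wiring with hubs, per-sign log-normal weights,
  modulatory and sub-threshold synapses) so everything runs and tests
  without any download.

## Worked example

```r
library(connres)

# a synthetic 1000-neuron connectome, ingested through the full pipeline
graph <- synthetic_graph(synth_config(n_neurons = 1000, seed = 42))
graph
#> connectome_graph: 1000 neurons, 5125 signed edges
#>   classes: ME (305), ME>LO (133), LO (76), bilateral (57), CX (48) ...

# carve a 200-neuron connected reservoir and rescale it
res <- select_most_connected(graph, 200) |>
  extract_weight_matrix() |>
  rescale_spectral()
res
#> reservoir_matrix: N = 200 , nnz = 780 (sparsity 0.981)
#>   criterion: most_connected
#>   spectral radius: 0.99

# the chaotic benchmark trajectory
traj <- propagate(c(-0.80, 0, 0, 0, -0.63, 0.08), steps = 10000)
traj
#> cr3bp_trajectory: 10000 samples, dt = 0.1 , mu = 0.01215059
#>   max Jacobi drift: 1.53e-10

# forecast one step ahead with the connectome reservoir ...
cfg <- esn_config(beta = 1e-6, horizon = 1)
set.seed(1)
forecast_trial(res, cfg, traj)
#> esn_trial: train nRMSE 0.003617, test nRMSE 0.005873 (600 parameters)

# ... and with a density-matched random control
ctrl <- randomize(res, "control_random", dist = "uniform")
set.seed(1)
forecast_trial(ctrl, cfg, traj)
#> esn_trial: train nRMSE 0.00961, test nRMSE 0.01564 (600 parameters)
```

Both trials share the trajectory and (via the seed) the input wiring; the
nRMSE is the root-mean-square prediction error relative to the mean
target norm, so `0.0059` means the connectome reservoir's one-step test
predictions are off by about 0.6% of the typical orbital distance, and
`600 parameters` is the 3 × N readout — the only thing trained. A full
comparison across sizes, regularizers, horizons and all five
architectures is one call: `run_grid(grid_spec(...), graph)`, then
`summarize_grid()` for means, standard errors, Mann–Whitney significance
versus the control, and Bhattacharyya distances between architectures.

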