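#' Monte Carlo grid specification
#'
#' Defaults mirror the full study design: reservoir sizes 50-1500, ridge
#' regularizers 1e-3/1e-6/1e-9, horizons 1/3/7/10, spectral radius 0.99
#' (sweep 0.25/0.5/0.75/0.99 available), five trajectories differing by a
#' 1% perturbation of the initial conditions, ten random re-initializations
#' each (50 cases per combination).
#'
#' @param sizes reservoir sizes N.
#' @param betas ridge regularizers.
#' @param horizons forecast horizons (timesteps).
#' @param spectral_radii reservoir spectral radii.
#' @param criteria subgraph selection criteria.
#' @param distributions weight distributions for freshly drawn weights.
#' @param architectures architectures to compare, see [ARCHITECTURES].
#' @param n_trajectories,trials_per_trajectory Monte Carlo repetitions.
#' @param state0 base CR3BP initial state `(x, y, z, vx, vy, vz)`.
#' @param steps trajectory length in samples.
#' @param washout_len,train_len,test_len trajectory split.
#' @param alpha,input_scaling ESN parameters.
#' @param seed master seed; the whole grid is reproducible from it.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(sizes = c(50, 100, 200, 500, 1000, 1500),
                      betas = c(1e-3, 1e-6, 1e-9),
                      horizons = c(1, 3, 7, 10),
                      spectral_radii = 0.99,
                      criteria = c("most_connected", "proportional"),
                      distributions = "uniform",
                      architectures = ARCHITECTURES,
                      n_trajectories = 5, trials_per_trajectory = 10,
                      state0 = c(-0.80, 0, 0, 0, -0.63, 0.08),
                      steps = 10000, washout_len = 500, train_len = 6500,
                      test_len = 3000, alpha = 0.9, input_scaling = 0.7,
                      seed = 1L) {
  stopifnot(length(sizes) > 0, length(betas) > 0, length(horizons) > 0,
            length(spectral_radii) > 0, trials_per_trajectory >= 1,
            n_trajectories >= 1)
  architectures <- match.arg(architectures, ARCHITECTURES,
                             several.ok = TRUE)
  structure(list(sizes = sizes, betas = betas, horizons = horizons,
                 spectral_radii = spectral_radii, criteria = criteria,
                 distributions = distributions,
                 architectures = architectures,
                 n_trajectories = n_trajectories,
                 trials_per_trajectory = trials_per_trajectory,
                 state0 = state0, steps = steps,
                 washout_len = washout_len, train_len = train_len,
                 test_len = test_len, alpha = alpha,
                 input_scaling = input_scaling, seed = as.integer(seed)),
            class = "grid_spec")
}

#' Run the Monte Carlo comparison grid
#'
#' For each (criterion, N) the connectome reservoir is selected once; for
#' each trajectory and trial, one input map and bias draw is shared across
#' all architectures (matched pairs), the control and hybrid variants are
#' derived with the connectome reservoir's sparsity and spectral radius,
#' and every (beta, horizon) readout is trained from the same reservoir
#' state run. Combinations whose N exceeds the graph are skipped with a
#' warning.
#'
#' @param spec a [grid_spec()].
#' @param graph a `connectome_graph` to carve reservoirs from.
#' @param trajectories optional pre-generated list of `cr3bp_trajectory`
#'   (default: generated from `spec$state0` with 1% perturbations).
#' @param progress print per-cell progress lines.
#' @return a `grid_result` data frame with one row per
#'   (criterion, N, spectral radius, distribution, trajectory, trial,
#'   architecture, beta, horizon) carrying train and test nRMSE.
#' @export
run_grid <- function(spec, graph, trajectories = NULL, progress = FALSE) {
  stopifnot(inherits(spec, "grid_spec"))
  set.seed(spec$seed)
  if (is.null(trajectories)) {
    trajectories <- make_trajectories(spec$state0, spec$n_trajectories,
                                      steps = spec$steps)
  }
  rows <- vector("list", 0)
  n_graph <- nrow(graph$nodes)
  for (crit in spec$criteria) {
    for (N in spec$sizes) {
      if (N > n_graph) {
        warning("skipping N = ", N, ": graph has only ", n_graph, " nodes")
        next
      }
      sub <- switch(crit,
                    most_connected = select_most_connected(graph, N),
                    proportional = select_proportional(graph, N),
                    stop("unknown criterion: ", crit))
      base_raw <- extract_weight_matrix(sub)
      for (rho in spec$spectral_radii) {
        base <- rescale_spectral(base_raw, rho)
        for (dist in spec$distributions) {
          for (traj_id in seq_along(trajectories)) {
            traj <- trajectories[[traj_id]]
            for (trial in seq_len(spec$trials_per_trajectory)) {
              imap <- build_input_map(N, spec$input_scaling)
              for (arch in spec$architectures) {
                Wa <- if (arch == "conn_topo_conn_weights") base
                      else randomize(base, arch, dist = dist, target = rho)
                cells <- eval_trial_cells(Wa, imap, traj, spec)
                for (cell in cells) {
                  rows[[length(rows) + 1L]] <- data.frame(
                    architecture = arch, criterion = crit, N = N,
                    beta = cell$beta, horizon = cell$horizon,
                    distribution = dist, spectral_radius = rho,
                    trajectory = traj_id, trial = trial,
                    train_nrmse = cell$train_nrmse,
                    test_nrmse = cell$test_nrmse,
                    seed = spec$seed, stringsAsFactors = FALSE)
                }
              }
              if (progress)
                message(sprintf("%s N=%d rho=%g %s traj=%d trial=%d done",
                                crit, N, rho, dist, traj_id, trial))
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("grid_result", class(out))
  out
}

# One reservoir run per (W, input map, trajectory); readouts for every
# (beta, horizon) reuse the same states, and the states-only Gram matrix is
# cached per horizon.
eval_trial_cells <- function(W, imap, traj, spec) {
  cfg0 <- esn_config(alpha = spec$alpha, input_scaling = spec$input_scaling,
                     beta = spec$betas[1], horizon = spec$horizons[1],
                     washout_len = spec$washout_len,
                     train_len = spec$train_len, test_len = spec$test_len)
  Wm <- if (inherits(W, "reservoir_matrix")) W$W else W
  need <- spec$washout_len + spec$train_len + spec$test_len
  pos <- traj$positions
  states <- run_reservoir(Wm, imap, pos[seq_len(need), , drop = FALSE],
                          alpha = spec$alpha)
  vis <- seq_len(nrow(Wm))
  cells <- list()
  for (h in spec$horizons) {
    cfg <- cfg0; cfg$horizon <- as.integer(h)
    tr_n <- spec$washout_len + seq_len(spec$train_len - h)
    G <- tcrossprod(states[vis, tr_n, drop = FALSE])
    for (beta in spec$betas) {
      cfg$beta <- beta
      tr <- trial_from_states(states, pos, cfg, vis, "states_only", imap,
                              G = G)
      cells[[length(cells) + 1L]] <- list(beta = beta, horizon = h,
                                          train_nrmse = tr$train_nrmse,
                                          test_nrmse = tr$test_nrmse)
    }
  }
  cells
}

#' Generate the study's perturbed trajectory family
#'
#' The first trajectory uses `state0` exactly; the rest perturb each
#' nonzero component by up to `fraction` (default 1%). Uses the current R
#' random stream.
#'
#' @param state0 base initial state.
#' @param n number of trajectories.
#' @param fraction relative perturbation bound.
#' @param steps,dt,mu passed to [propagate()].
#' @return list of `cr3bp_trajectory`.
#' @export
make_trajectories <- function(state0, n, fraction = 0.01, steps = 10000,
                              dt = 0.1, mu = MU_EARTH_MOON) {
  lapply(seq_len(n), function(i) {
    s <- if (i == 1) state0 else perturb_initial(state0, fraction)
    propagate(s, mu = mu, dt = dt, steps = steps)
  })
}

#' Mann-Whitney U test (rank sum, midrank ties)
#'
#' Two-sided p-value from the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b numeric samples.
#' @return list with `U` (statistic of the first sample) and `p_value`.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))               # midranks
  Ra <- sum(r[seq_len(na)])
  U <- Ra - na * (na + 1) / 2
  mu <- na * nb / 2
  nties <- table(r)
  n <- na + nb
  sigma2 <- na * nb / 12 * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  if (sigma2 == 0) return(list(U = U, p_value = 1))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Bhattacharyya distance between two empirical distributions
#'
#' Both samples are binned on a shared-range histogram (`n_bins` equal-width
#' bins over the pooled range), normalized to probability vectors p and q,
#' and `DB = -ln(sum_i sqrt(p_i q_i))`. Symmetric, non-negative, zero iff
#' the binned distributions coincide; `Inf` when the supports are disjoint.
#'
#' @param a,b numeric samples.
#' @param n_bins number of histogram bins.
#' @return non-negative scalar (possibly `Inf`).
#' @export
bhattacharyya_distance <- function(a, b, n_bins = 10) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  rng <- range(c(a, b))
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  p <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) / length(a)
  q <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) / length(b)
  bc <- sum(sqrt(p * q))
  if (bc == 0) return(Inf)
  -log(bc)
}

#' Whole-connectome trial with class-restricted input and output
#'
#' Uses the entire graph as the reservoir: only neurons in the input
#' classes receive the signal (all other input rows zero), and only
#' neurons in the output classes feed the readout, so the trainable
#' parameter count is three times the output-class census. The class map
#' defaults to the study's sensory-input / readout-output partition.
#'
#' @param graph a `connectome_graph`.
#' @param config an [esn_config()].
#' @param class_map list with character vectors `input`, `intermediate`,
#'   `output` partitioning the classes present in the graph.
#' @param traj a `cr3bp_trajectory`.
#' @param target spectral radius for the reservoir.
#' @return an `esn_trial`; its `n_params` equals `3 *` the number of
#'   output-class neurons.
#' @export
full_connectome_trial <- function(graph, config, traj,
                                  class_map = default_class_map(),
                                  target = 0.99) {
  res <- rescale_spectral(extract_weight_matrix(graph), target)
  cl <- res$class_labels
  present <- unique(cl)
  mapped <- unlist(class_map, use.names = FALSE)
  unknown <- setdiff(present, mapped)
  if (length(unknown))
    stop("classes not covered by the class map: ",
         paste(unknown, collapse = ", "))
  input_idx <- which(cl %in% class_map$input)
  output_idx <- which(cl %in% class_map$output)
  if (!length(input_idx)) stop("no neurons in the input classes")
  if (!length(output_idx)) stop("no neurons in the output classes")
  imap <- build_input_map(nrow(res$W), config$input_scaling,
                          input_nodes = input_idx)
  forecast_trial(res, config, traj, input_map = imap,
                 visible_index = output_idx)
}

#' Default input/intermediate/output class partition
#'
#' Sensory classes drive the reservoir; learning- and hormone-associated
#' readout classes feed the trained layer; the rest are intermediate.
#'
#' @return list with `input`, `intermediate`, `output` label vectors.
#' @export
default_class_map <- function() {
  list(
    input = c("olfactory", "visual", "mechanosensory", "hygrosensory",
              "thermosensory", "gustatory", "ocellar", "unknown sensory"),
    intermediate = c("CX", "ALPN", "LO", "bilateral", "ME", "ME>LOP",
                     "ME>LO", "LO>LOP", "ME>LA", "LA>ME", "ME>LO.LOP",
                     "ALLN", "LOP>ME.LO", "LA", "AN", "ALIN", "mAL",
                     "LHLN", "ME.LO", "ME.LO.LOP", "LO>ME", "optic lobes",
                     "ME.LOP", "TPN"),
    output = c("MBON", "DAN", "LHCENT", "clock", "pars intercerebralis",
               "pars lateralis", "Kenyon Cell", "ALON", "LOP>ME",
               "LOP>LO.ME", "LOP>LO", "LOP", "TuBu"))
}

#' Summarize a grid result
#'
#' Per (criterion, N, beta, horizon, distribution, spectral radius,
#' architecture): mean train/test nRMSE and the standard deviation of the
#' mean. Each non-control architecture is compared with the control in the
#' same cell by the Mann-Whitney test (significance at p < 0.05) and by
#' the Bhattacharyya distance between the pooled test-nRMSE distributions
#' averaged over N and beta.
#'
#' @param results a `grid_result`.
#' @param control architecture used as the comparison baseline.
#' @return list with `cells` (per-cell summary data frame, with MWW
#'   p-values and significance flags vs the control) and `bhattacharyya`
#'   (per architecture pair mean and sd over N and beta).
#' @export
summarize_grid <- function(results, control = "control_random") {
  key_cols <- c("criterion", "N", "beta", "horizon", "distribution",
                "spectral_radius")
  cell_key <- interaction(results[key_cols], drop = TRUE)
  out <- list()
  for (k in levels(cell_key)) {
    cell <- results[cell_key == k, , drop = FALSE]
    ctrl <- cell$test_nrmse[cell$architecture == control]
    for (arch in unique(cell$architecture)) {
      x <- cell[cell$architecture == arch, , drop = FALSE]
      n <- nrow(x)
      if (n == 1) warning("single-trial cell; std of mean reported as 0")
      p <- if (arch != control && length(ctrl))
        mann_whitney_u(x$test_nrmse, ctrl)$p_value else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        x[1, key_cols], architecture = arch, n_trials = n,
        mean_train_nrmse = mean(x$train_nrmse),
        mean_test_nrmse = mean(x$test_nrmse),
        sem_test_nrmse = if (n > 1) stats::sd(x$test_nrmse) / sqrt(n) else 0,
        p_vs_control = p,
        significant = !is.na(p) & p < 0.05,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, out)
  rownames(cells) <- NULL
  # Bhattacharyya distances between architectures, per (N, beta) then
  # averaged over those two dimensions
  archs <- unique(results$architecture)
  pairs <- utils::combn(archs, 2, simplify = FALSE)
  bh <- lapply(pairs, function(pr) {
    nb_key <- interaction(results$N, results$beta, drop = TRUE)
    d <- vapply(levels(nb_key), function(k) {
      sub <- results[nb_key == k, ]
      a <- sub$test_nrmse[sub$architecture == pr[1]]
      b <- sub$test_nrmse[sub$architecture == pr[2]]
      if (!length(a) || !length(b)) return(NA_real_)
      bhattacharyya_distance(a, b)
    }, 0)
    d <- d[is.finite(d)]
    data.frame(arch_a = pr[1], arch_b = pr[2],
               mean_db = mean(d), sd_db = stats::sd(d),
               stringsAsFactors = FALSE)
  })
  list(cells = cells, bhattacharyya = do.call(rbind, bh))
}
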