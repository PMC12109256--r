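test_that("Mann-Whitney U matches identities and the permutation oracle", {
  a <- c(1.2, 3.4, 2.2, 5.5)
  m <- mann_whitney_u(a, a)
  expect_gt(m$p_value, 0.9)
  # U_a + U_b == n_a * n_b
  set.seed(19)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    ua <- mann_whitney_u(x, y)$U
    ub <- mann_whitney_u(y, x)$U
    expect_equal(ua + ub, length(x) * length(y))
  }
  # disjoint 4 vs 4: exact permutation enumeration, two decimals
  x <- c(1, 2, 3, 4); y <- c(10, 11, 12, 13)
  expect_lt(abs(mann_whitney_u(x, y)$p_value - exact_mww_p(x, y)), 0.005)
  # moderate separation against the oracle too
  x2 <- c(1.1, 2.3, 9.9, 4.2, 5.0); y2 <- c(3.3, 6.6, 7.7, 8.8)
  expect_lt(abs(mann_whitney_u(x2, y2)$p_value - exact_mww_p(x2, y2)), 0.05)
  # cross-check against the standard library implementation
  w <- suppressWarnings(stats::wilcox.test(x2, y2, exact = FALSE,
                                           correct = TRUE))
  expect_equal(mann_whitney_u(x2, y2)$p_value, w$p.value, tolerance = 1e-6)
  expect_error(mann_whitney_u(numeric(), y), "non-empty")
})

test_that("Bhattacharyya distance reproduces hand-computed overlaps", {
  set.seed(23)
  a <- rnorm(100)
  expect_equal(bhattacharyya_distance(a, a), 0)
  expect_equal(bhattacharyya_distance(runif(50, 0, 1), runif(50, 10, 11)),
               Inf)
  # three-bin hand histogram: (0.5, 0.3, 0.2) vs (0.4, 0.4, 0.2)
  a3 <- c(rep(0.5, 5), rep(1.5, 3), rep(2.5, 2))
  b3 <- c(rep(0.5, 4), rep(1.5, 4), rep(2.5, 2))
  want <- -log(sqrt(0.20) + sqrt(0.12) + sqrt(0.04))
  expect_equal(bhattacharyya_distance(a3, b3, n_bins = 3), want,
               tolerance = 1e-12)
  # symmetry
  x <- rnorm(60); y <- rnorm(60, 1)
  expect_equal(bhattacharyya_distance(x, y), bhattacharyya_distance(y, x))
})

make_small_grid <- function(archs = c("control_random",
                                      "conn_topo_conn_weights"),
                            sizes = 30, betas = 1e-6, horizons = 1,
                            n_traj = 5, trials = 10, seed = 77) {
  grid_spec(sizes = sizes, betas = betas, horizons = horizons,
            criteria = "most_connected", architectures = archs,
            n_trajectories = n_traj, trials_per_trajectory = trials,
            steps = 1200, washout_len = 100, train_len = 800,
            test_len = 300, seed = seed)
}

test_that("grid row count is the product of its dimensions", {
  g <- withr::with_seed(55, random_connected_graph(60, extra = 400))
  spec <- make_small_grid()
  res <- run_grid(spec, g)
  expect_equal(nrow(res), 1 * 1 * 1 * 2 * 5 * 10)
  expect_true(all(is.finite(res$train_nrmse)))
  expect_true(all(is.finite(res$test_nrmse)))
})

test_that("grids are reproducible bit-for-bit under the master seed", {
  g <- withr::with_seed(56, random_connected_graph(50, extra = 300))
  spec <- make_small_grid(n_traj = 2, trials = 2, seed = 123)
  r1 <- run_grid(spec, g)
  r2 <- run_grid(spec, g)
  expect_identical(r1, r2)
})

test_that("infeasible sizes are skipped with a warning", {
  g <- withr::with_seed(57, random_connected_graph(40, extra = 200))
  spec <- make_small_grid(sizes = c(30, 500), n_traj = 1, trials = 1)
  expect_warning(res <- run_grid(spec, g), "skipping")
  expect_equal(unique(res$N), 30)
})

test_that("summaries flag injected shifts and stay quiet under the null", {
  fake <- function(shift, n = 25, seed = 1) {
    set.seed(seed)
    base <- expand.grid(trial = 1:n,
                        architecture = c("control_random", "other"),
                        stringsAsFactors = FALSE)
    base$criterion <- "most_connected"; base$N <- 100
    base$beta <- 1e-6; base$horizon <- 1
    base$distribution <- "uniform"; base$spectral_radius <- 0.99
    base$trajectory <- 1
    base$train_nrmse <- rnorm(nrow(base), 0.5, 0.1)
    base$test_nrmse <- rnorm(nrow(base), 0.5, 0.1) +
      ifelse(base$architecture == "other", shift, 0)
    base
  }
  # 3-sigma shift detected in at least 90% of seeded repeats
  hits <- vapply(1:20, function(s) {
    sm <- summarize_grid(fake(0.3, seed = s))
    any(sm$cells$significant, na.rm = TRUE)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # identical architectures: no significance
  same <- fake(0)
  same$test_nrmse <- rep(rnorm(25, 0.5, 0.1), 2)
  expect_false(any(summarize_grid(same)$cells$significant, na.rm = TRUE))
  # single-trial cells warn and report zero sem
  one <- fake(0, n = 1)
  w <- capture_warnings(sm1 <- summarize_grid(one))
  expect_match(w, "single-trial", all = TRUE)
  expect_gt(length(w), 0)
  expect_equal(sm1$cells$sem_test_nrmse, c(0, 0))
})

test_that("false-positive rate under the global null is near 5 percent", {
  ps <- vapply(1:250, function(s) {
    set.seed(3000 + s)
    mann_whitney_u(rnorm(25), rnorm(25))$p_value
  }, 0)
  frac <- mean(ps < 0.05)
  se <- sqrt(0.05 * 0.95 / 250)
  expect_lt(abs(frac - 0.05), 3 * se + 0.01)
})

test_that("whole-connectome trials restrict input and readout by class", {
  g <- synthetic_graph(synth_config(n_neurons = 400, seed = 60))
  cfg <- esn_config(beta = 1e-6, horizon = 1, washout_len = 100,
                    train_len = 800, test_len = 300)
  traj <- short_cr3bp()
  cmap <- default_class_map()
  n_out <- sum(g$nodes$cell_class %in% cmap$output)
  withr::with_seed(61, tr <- full_connectome_trial(g, cfg, traj, cmap))
  expect_equal(tr$n_params, 3 * n_out)
  expect_true(is.finite(tr$train_nrmse) && is.finite(tr$test_nrmse))
  # all classes marked output reduces to the standard trial
  all_out <- list(input = unique(g$nodes$cell_class),
                  intermediate = character(),
                  output = unique(g$nodes$cell_class))
  withr::with_seed(62, tr2 <- full_connectome_trial(g, cfg, traj, all_out))
  expect_equal(tr2$n_params, 3 * nrow(g$nodes))
  # empty output classes rejected
  no_out <- list(input = unique(g$nodes$cell_class),
                 intermediate = character(), output = "nothing")
  expect_error(full_connectome_trial(g, cfg, traj, no_out), "output")
})

test_that("Bhattacharyya summary aggregates over sizes and regularizers", {
  set.seed(71)
  rows <- expand.grid(trial = 1:10, N = c(50, 100), beta = c(1e-3, 1e-6),
                      architecture = c("control_random", "other"),
                      stringsAsFactors = FALSE)
  rows$criterion <- "most_connected"; rows$horizon <- 1
  rows$distribution <- "uniform"; rows$spectral_radius <- 0.99
  rows$trajectory <- 1
  rows$train_nrmse <- rnorm(nrow(rows), 0.5, 0.05)
  rows$test_nrmse <- rnorm(nrow(rows), 0.5, 0.05) +
    ifelse(rows$architecture == "other", 0.08, 0)
  sm <- suppressWarnings(summarize_grid(rows))
  expect_equal(nrow(sm$bhattacharyya), 1)
  expect_gt(sm$bhattacharyya$mean_db, 0)
})
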