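test_that("input map wires each neuron to exactly one coordinate", {
  withr::with_seed(2, m <- build_input_map(3000))
  counts <- table(m$assignment)
  expect_equal(sum(counts), 3000)
  # binomial concentration: each coordinate near 1000
  expect_true(all(abs(counts - 1000) < 3 * sqrt(3000 * (1 / 3) * (2 / 3))))
  expect_true(all(rowSums(m$Win[, 2:4] != 0) == 1))
  expect_true(all(abs(m$Win) <= 0.7))
  withr::with_seed(2, m2 <- build_input_map(3000))
  expect_identical(m$Win, m2$Win)
  expect_equal(max(abs(build_input_map(10, input_scaling = 0)$Win)), 0)
  # restricted input nodes leave the others all-zero
  withr::with_seed(5, mr <- build_input_map(10, input_nodes = c(2, 7)))
  expect_equal(rowSums(mr$Win[-c(2, 7), ] != 0), rep(0, 8))
  expect_error(build_input_map(10, input_nodes = integer()), "non-empty")
})

test_that("reservoir recurrence matches a hand-unrolled reference", {
  # alpha = 0 freezes the state
  withr::with_seed(1, imap <- build_input_map(4))
  W <- rescale_spectral(Matrix::Matrix(matrix(rnorm(16), 4), sparse = TRUE))
  u <- matrix(rnorm(30), 10, 3)
  x0 <- runif(4)
  st <- run_reservoir(W, imap, u, alpha = 0, x0 = x0)
  expect_equal(st, matrix(x0, 4, 10), ignore_attr = TRUE)
  # zero weights, zero input map: states stay at zero
  z <- run_reservoir(Matrix::Matrix(0, 4, 4, sparse = TRUE),
                     list(Win = matrix(0, 4, 4)), u, alpha = 0.9)
  expect_equal(max(abs(z)), 0)
  # single neuron, scalar recurrence unrolled manually in R
  Win1 <- matrix(c(0.2, 0.5, 0, 0), 1, 4)
  uc <- matrix(rep(c(0.3, -0.1, 0.2), each = 20), 20, 3)
  got <- run_reservoir(matrix(0.5, 1, 1), list(Win = Win1), uc, alpha = 0.9)
  x <- 0
  ref <- numeric(20)
  for (n in 1:20) {
    x <- 0.1 * x + 0.9 * tanh(0.5 * x + 0.2 + 0.5 * 0.3)
    ref[n] <- x
  }
  expect_equal(as.numeric(got), ref, tolerance = 1e-12)
})

test_that("reservoir states fade the initial condition (echo state)", {
  withr::with_seed(9, {
    W <- rescale_spectral(Matrix::rsparsematrix(80, 80, 0.1), 0.5)
    imap <- build_input_map(80)
    u <- matrix(rnorm(600), 200, 3)
  })
  s1 <- run_reservoir(W, imap, u, x0 = rep(0.9, 80))
  s2 <- run_reservoir(W, imap, u, x0 = rep(-0.9, 80))
  expect_lt(max(abs(s1[, 200] - s2[, 200])), 1e-6)
})

test_that("ridge readout solves the regularized normal equations", {
  withr::with_seed(3, {
    X <- matrix(rnorm(20 * 200), 20, 200)
    Wtrue <- matrix(rnorm(60), 3, 20)
  })
  Y <- Wtrue %*% X
  # exact recovery at beta = 0 on a well-conditioned system
  ro <- train_readout(X, Y, beta = 0)
  expect_equal(ro$Wout, Wtrue, tolerance = 1e-8)
  expect_lt(nrmse(Y, predict_readout(ro, X)), 1e-10)
  expect_equal(ro$n_params, 60)
  # heavy shrinkage drives the weights to zero
  ro2 <- train_readout(X, Y, beta = 1e12)
  expect_lt(max(abs(ro2$Wout)), 1e-6)
  # independent oracle: explicit normal-equation solve
  beta <- 0.37
  ro3 <- train_readout(X, Y, beta = beta)
  oracle <- Y %*% t(X) %*% solve(X %*% t(X) + beta * diag(20))
  expect_equal(ro3$Wout, oracle, tolerance = 1e-10)
  # normal-equation residual bound
  res <- ro3$Wout %*% (X %*% t(X) + beta * diag(20)) - Y %*% t(X)
  expect_lt(max(abs(res)) / max(abs(Y %*% t(X))), 1e-8)
  # singular system at beta = 0 advises regularizing
  Xs <- matrix(1, 5, 50)
  expect_error(train_readout(Xs, matrix(1, 3, 50), beta = 0), "beta > 0")
  # full regressor mode includes bias and input feedthrough rows
  U <- matrix(rnorm(600), 3, 200)
  ro4 <- train_readout(X, Y, beta = 1e-6, mode = "full_regressor", U = U)
  expect_equal(dim(ro4$Wout), c(3L, 24L))
})

test_that("nRMSE is positive definite, scale invariant, exact on closed form", {
  withr::with_seed(6, {
    Y <- matrix(rnorm(30), 3, 10)
    Yh <- Y + matrix(rnorm(30, sd = 0.1), 3, 10)
  })
  expect_equal(nrmse(Y, Y), 0)
  v <- nrmse(Y, Yh)
  expect_gt(v, 0)
  expect_equal(nrmse(7 * Y, 7 * Yh), v, tolerance = 1e-12)
  # constant target norm c with offset d on one coordinate: d / (c sqrt(3))
  cnorm <- 2; d <- 0.25
  Yc <- matrix(c(cnorm, 0, 0), 3, 50)
  Yhc <- Yc + matrix(c(0, d, 0), 3, 50)
  expect_equal(nrmse(Yc, Yhc), d / (cnorm * sqrt(3)), tolerance = 1e-12)
  expect_error(nrmse(matrix(0, 3, 4), matrix(1, 3, 4)), "all-zero")
  expect_error(nrmse(Y, Yh[, 1:5]), "shapes")
})

test_that("forecast trials are deterministic and fit constant signals", {
  cfg <- esn_config(beta = 1e-10, horizon = 1, washout_len = 50,
                    train_len = 300, test_len = 100)
  withr::with_seed(13, W <- rescale_spectral(Matrix::rsparsematrix(30, 30, 0.2)))
  tr <- constant_trajectory(450)
  withr::with_seed(1, t1 <- forecast_trial(W, cfg, tr))
  expect_lt(t1$test_nrmse, 1e-6)
  withr::with_seed(1, t2 <- forecast_trial(W, cfg, tr))
  expect_identical(t1$test_nrmse, t2$test_nrmse)
  expect_equal(t1$n_params, 90)  # 3 x N trainable parameters
  expect_error(forecast_trial(W, esn_config(horizon = 200, washout_len = 50,
                                            train_len = 300, test_len = 100),
                              tr), "horizon")
})

test_that("a modest reservoir forecasts the three-body series sanely", {
  traj <- short_cr3bp()
  cfg <- esn_config(beta = 1e-6, horizon = 1, washout_len = 200,
                    train_len = 2000, test_len = 700)
  g <- withr::with_seed(22, random_connected_graph(200, extra = 2000))
  W <- rescale_spectral(extract_weight_matrix(g))
  reps <- vapply(1:5, function(i) {
    withr::with_seed(100 + i, tr <- forecast_trial(W, cfg, traj))
    c(tr$train_nrmse, tr$test_nrmse)
  }, numeric(2))
  expect_true(all(is.finite(reps)))
  expect_true(all(reps[2, ] < 1))
  # training error at or below test error on most repeats
  expect_gte(mean(reps[1, ] <= reps[2, ]), 0.8)
})
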