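#' ESN hyperparameter configuration
#'
#' @param alpha state-update mixing coefficient in `[0, 1]`; `1 - alpha` is
#'   the leakage rate. Default 0.9 (one minus the trajectory timestep).
#' @param input_scaling magnitude bound on input weights and biases
#'   (default 0.7).
#' @param beta ridge regularizer, `>= 0`.
#' @param horizon forecast offset in timesteps, `>= 1`.
#' @param washout_len,train_len,test_len trajectory split (samples).
#' @return an `esn_config` list.
#' @export
esn_config <- function(alpha = 0.9, input_scaling = 0.7, beta = 1e-6,
                       horizon = 1, washout_len = 500, train_len = 6500,
                       test_len = 3000) {
  stopifnot(alpha >= 0, alpha <= 1, input_scaling >= 0, beta >= 0,
            horizon >= 1)
  structure(list(alpha = alpha, input_scaling = input_scaling, beta = beta,
                 horizon = as.integer(horizon),
                 washout_len = as.integer(washout_len),
                 train_len = as.integer(train_len),
                 test_len = as.integer(test_len)),
            class = "esn_config")
}

#' Build the random input map
#'
#' Every input-receiving neuron is wired to exactly one of the three
#' Cartesian coordinates, chosen uniformly at random (so roughly a third of
#' the neurons see each coordinate); its input weight and bias are drawn
#' uniform(-1, 1) times `input_scaling`. Neurons outside `input_nodes`
#' get an all-zero row. Uses the current R random stream.
#'
#' @param N reservoir size.
#' @param input_scaling input weight magnitude bound.
#' @param input_nodes indices of neurons that receive input (default all).
#' @return an `input_map`: list with `Win` (N x 4; column 1 = bias) and
#'   `assignment` (coordinate index per neuron, NA for non-input nodes).
#' @export
build_input_map <- function(N, input_scaling = 0.7,
                            input_nodes = seq_len(N)) {
  stopifnot(N >= 1)
  input_nodes <- as.integer(input_nodes)
  if (!length(input_nodes)) stop("input_nodes must be non-empty")
  stopifnot(all(input_nodes >= 1 & input_nodes <= N))
  assignment <- rep(NA_integer_, N)
  assignment[input_nodes] <- sample.int(3, length(input_nodes),
                                        replace = TRUE)
  Win <- matrix(0, N, 4)
  Win[input_nodes, 1] <- runif(length(input_nodes), -1, 1) * input_scaling
  w <- runif(length(input_nodes), -1, 1) * input_scaling
  Win[cbind(input_nodes, assignment[input_nodes] + 1L)] <- w
  structure(list(Win = Win, assignment = assignment), class = "input_map")
}

#' Run the leaky reservoir over an input series
#'
#' Applies `x_n = (1 - alpha) x_{n-1} + alpha tanh(W x_{n-1} + Win [1; u_n])`
#' for n = 1..T.
#'
#' @param W square reservoir matrix (sparse or dense) or
#'   `reservoir_matrix`, already rescaled.
#' @param input_map an `input_map` from [build_input_map()].
#' @param inputs T x 3 input series.
#' @param alpha mixing coefficient.
#' @param x0 initial state (default zero vector).
#' @return N x T matrix of reservoir states.
#' @export
run_reservoir <- function(W, input_map, inputs, alpha = 0.9, x0 = NULL) {
  if (inherits(W, "reservoir_matrix")) W <- W$W
  N <- nrow(W)
  if (ncol(W) != N) stop("W must be square")
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != 3) stop("inputs must be a T x 3 series")
  if (nrow(input_map$Win) != N)
    stop("input map size (", nrow(input_map$Win),
         ") does not match reservoir size (", N, ")")
  if (is.null(x0)) x0 <- numeric(N)
  if (length(x0) != N) stop("x0 length must match reservoir size")
  Ws <- methods::as(methods::as(W, "CsparseMatrix"), "generalMatrix")
  cpp_run_reservoir(Ws, input_map$Win, inputs, alpha, as.numeric(x0))
}

#' Train the linear readout by one-shot ridge regression
#'
#' Solves `Wout = Y R' (R R' + beta I)^-1` where the regressor R is either
#' the raw visible states (`states_only`, default; 3 trained parameters per
#' visible neuron) or the stacked `[1; x; u]` (`full_regressor`).
#'
#' @param X K x T matrix of reservoir states restricted to the
#'   readout-visible neurons.
#' @param Y 3 x T target matrix.
#' @param beta ridge regularizer.
#' @param mode regressor layout.
#' @param U 3 x T input matrix, required for `full_regressor`.
#' @return a `readout`: list with `Wout`, `mode`, `n_params`.
#' @export
train_readout <- function(X, Y, beta, mode = c("states_only",
                                               "full_regressor"),
                          U = NULL) {
  mode <- match.arg(mode)
  stopifnot(ncol(X) == ncol(Y), beta >= 0)
  R <- switch(mode,
    states_only = X,
    full_regressor = {
      if (is.null(U)) stop("full_regressor mode requires U")
      rbind(1, X, U)
    })
  G <- tcrossprod(R) + diag(beta, nrow(R))
  Wout <- tryCatch(t(solve(G, tcrossprod(R, Y))),
                   error = function(e)
                     stop("ridge system is singular; use beta > 0 ",
                          "(solver said: ", conditionMessage(e), ")"))
  structure(list(Wout = Wout, mode = mode,
                 n_params = length(Wout)), class = "readout")
}

#' Apply a trained readout to states
#'
#' @param readout a `readout`.
#' @param X K x T visible states.
#' @param U 3 x T inputs (only for `full_regressor` readouts).
#' @return 3 x T predictions.
#' @export
predict_readout <- function(readout, X, U = NULL) {
  R <- switch(readout$mode,
    states_only = X,
    full_regressor = {
      if (is.null(U)) stop("full_regressor mode requires U")
      rbind(1, X, U)
    })
  readout$Wout %*% R
}

#' Normalized root mean squared error
#'
#' Default definition: the root mean square of all prediction errors
#' divided by the time-mean of the Euclidean norms of the target vectors —
#' non-negative, zero iff exact, invariant to a common positive rescaling
#' of targets and predictions. `literal = TRUE` instead evaluates the raw
#' quotient of the summed squared error over the scalar mean of the
#' targets (the naive reading of the printed formula; not scale-invariant).
#'
#' @param Y 3 x T targets, not identically zero.
#' @param Yhat 3 x T predictions.
#' @param literal use the literal quotient instead of the normalized RMS.
#' @return non-negative scalar.
#' @export
nrmse <- function(Y, Yhat, literal = FALSE) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("Y and Yhat shapes differ")
  if (all(Y == 0)) stop("all-zero targets; normalization undefined")
  if (literal) return(sum((Y - Yhat)^2) / mean(Y))
  sqrt(mean((Y - Yhat)^2)) / mean(sqrt(colSums(Y^2)))
}

#' Run one forecasting trial
#'
#' Feeds the full trajectory through the reservoir in one continuous run,
#' discards the washout states, trains the readout on the training window
#' to predict the position `horizon` steps ahead (open-loop direct
#' forecasting: input u_n, target u_{n+h}), and evaluates the nRMSE on the
#' training and test windows.
#'
#' @param W reservoir matrix (rescaled) or `reservoir_matrix`.
#' @param config an [esn_config()].
#' @param traj a `cr3bp_trajectory`.
#' @param input_map optional pre-built `input_map` (matched-pair reuse);
#'   drawn fresh from the current random stream when `NULL`.
#' @param visible_index neurons feeding the readout (default all).
#' @param mode readout regressor layout, see [train_readout()].
#' @return an `esn_trial`: list with `train_nrmse`, `test_nrmse`,
#'   `n_params`, the config and the readout.
#' @export
forecast_trial <- function(W, config, traj, input_map = NULL,
                           visible_index = NULL, mode = "states_only") {
  Wm <- if (inherits(W, "reservoir_matrix")) W$W else W
  N <- nrow(Wm)
  h <- config$horizon
  if (h >= config$train_len || h >= config$test_len)
    stop("horizon (", h, ") must be shorter than both the train and test ",
         "segments")
  if (is.null(input_map))
    input_map <- build_input_map(N, config$input_scaling)
  if (is.null(visible_index)) visible_index <- seq_len(N)
  pos <- traj$positions
  Tn <- nrow(pos)
  need <- config$washout_len + config$train_len + config$test_len
  if (need > Tn) stop("trajectory too short for the configured split")
  states <- run_reservoir(Wm, input_map, pos[seq_len(need), , drop = FALSE],
                          alpha = config$alpha)
  trial_from_states(states, pos, config, visible_index, mode, input_map)
}

# Shared trainer/evaluator: states already computed for the full series.
trial_from_states <- function(states, pos, config, visible_index, mode,
                              input_map, G = NULL) {
  h <- config$horizon
  w <- config$washout_len; trn <- config$train_len; ten <- config$test_len
  tr_n <- w + seq_len(trn - h)          # regressor columns, train
  te_n <- w + trn + seq_len(ten - h)    # regressor columns, test
  Xtr <- states[visible_index, tr_n, drop = FALSE]
  Xte <- states[visible_index, te_n, drop = FALSE]
  Ytr <- t(pos[tr_n + h, , drop = FALSE])
  Yte <- t(pos[te_n + h, , drop = FALSE])
  Utr <- t(pos[tr_n, , drop = FALSE])
  Ute <- t(pos[te_n, , drop = FALSE])
  ro <- if (mode == "states_only" && !is.null(G)) {
    Wout <- tryCatch(t(solve(G + diag(config$beta, nrow(Xtr)),
                             tcrossprod(Xtr, Ytr))),
                     error = function(e)
                       stop("ridge system is singular; use beta > 0"))
    structure(list(Wout = Wout, mode = "states_only",
                   n_params = length(Wout)), class = "readout")
  } else train_readout(Xtr, Ytr, config$beta, mode = mode, U = Utr)
  structure(list(
    train_nrmse = nrmse(Ytr, predict_readout(ro, Xtr, Utr)),
    test_nrmse = nrmse(Yte, predict_readout(ro, Xte, Ute)),
    n_params = ro$n_params, config = config, readout = ro,
    n_visible = length(visible_index)), class = "esn_trial")
}

#' @export
print.esn_trial <- function(x, ...) {
  cat(sprintf("esn_trial: train nRMSE %.4g, test nRMSE %.4g (%d parameters)\n",
              x$train_nrmse, x$test_nrmse, x$n_params))
  invisible(x)
}
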