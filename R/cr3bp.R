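#' Propagate a circularly-restricted three-body-problem trajectory
#'
#' Integrates the rotating-frame CR3BP equations of motion
#' \deqn{\ddot x - 2\dot y = x - (1-\mu)(x+\mu)/r_1^3 - \mu(x-1+\mu)/r_2^3}
#' \deqn{\ddot y + 2\dot x = y - (1-\mu)y/r_1^3 - \mu y/r_2^3}
#' \deqn{\ddot z = -(1-\mu)z/r_1^3 - \mu z/r_2^3}
#' with \eqn{r_1, r_2} the distances to the primaries at \eqn{(-\mu,0,0)}
#' and \eqn{(1-\mu,0,0)}, in normalized units (separation 1, angular rate
#' 1). Adaptive high-order stepping (lsoda) sampled every `dt`; the Jacobi
#' constant is evaluated at every sample and its maximum drift recorded.
#'
#' @param state0 numeric 6-vector `(x, y, z, vx, vy, vz)`.
#' @param mu mass ratio in `[0, 0.5]`; default is the earth-moon system.
#' @param dt sampling step in normalized time units.
#' @param steps number of datapoints (the initial state is the first).
#' @param rtol,atol integrator tolerances.
#' @return a `cr3bp_trajectory`: list with `positions` (steps x 3),
#'   `velocities`, `times`, `dt`, `mu` and `provenance` (initial state,
#'   tolerances, max Jacobi drift).
#' @export
propagate <- function(state0, mu = MU_EARTH_MOON, dt = 0.1, steps = 10000,
                      rtol = 1e-12, atol = 1e-12) {
  stopifnot(length(state0) == 6, all(is.finite(state0)),
            mu >= 0, mu <= 0.5, steps >= 1)
  times <- (seq_len(steps) - 1) * dt
  guard <- function(s, label) {
    r1 <- sqrt((s[1] + mu)^2 + s[2]^2 + s[3]^2)
    r2 <- sqrt((s[1] - 1 + mu)^2 + s[2]^2 + s[3]^2)
    # only massive primaries are singular (mu = 0 leaves the second empty)
    if ((mu < 1 && r1 < 1e-6) || (mu > 0 && r2 < 1e-6))
      stop("close approach to a primary (r < 1e-6) at ", label)
  }
  guard(state0, "the initial state")
  rhs <- function(t, s, p) {
    r1sq <- (s[1] + mu)^2 + s[2]^2 + s[3]^2
    r2sq <- (s[1] - 1 + mu)^2 + s[2]^2 + s[3]^2
    r13 <- r1sq * sqrt(r1sq); r23 <- r2sq * sqrt(r2sq)
    # a massless primary exerts no force (avoids 0/0 at its location)
    g1 <- if (mu < 1) (1 - mu) / r13 else 0
    g2 <- if (mu > 0) mu / r23 else 0
    list(c(s[4], s[5], s[6],
           2 * s[5] + s[1] - g1 * (s[1] + mu) - g2 * (s[1] - 1 + mu),
           -2 * s[4] + s[2] - g1 * s[2] - g2 * s[2],
           -g1 * s[3] - g2 * s[3]))
  }
  sol <- deSolve::ode(y = as.numeric(state0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (nrow(sol) < steps) stop("integration failed before ", steps, " steps")
  S <- unname(sol[, 2:7, drop = FALSE])
  r1 <- sqrt((S[, 1] + mu)^2 + S[, 2]^2 + S[, 3]^2)
  r2 <- sqrt((S[, 1] - 1 + mu)^2 + S[, 2]^2 + S[, 3]^2)
  if (mu == 0) r2 <- Inf
  close_idx <- which(pmin(r1, r2) < 1e-6)
  if (length(close_idx))
    stop("close approach to a primary (r < 1e-6) at step ", close_idx[1])
  C <- apply(S, 1, jacobi_constant, mu = mu)
  structure(list(positions = S[, 1:3, drop = FALSE],
                 velocities = S[, 4:6, drop = FALSE],
                 times = times, dt = dt, mu = mu,
                 provenance = list(state0 = as.numeric(state0),
                                   rtol = rtol, atol = atol,
                                   jacobi_drift = max(abs(C - C[1])))),
            class = "cr3bp_trajectory")
}

#' Earth-moon CR3BP mass ratio
#' @export
MU_EARTH_MOON <- 0.0121505856

#' @export
print.cr3bp_trajectory <- function(x, ...) {
  cat("cr3bp_trajectory:", nrow(x$positions), "samples, dt =", x$dt,
      ", mu =", x$mu, "\n  max Jacobi drift:",
      format(x$provenance$jacobi_drift, digits = 3), "\n")
  invisible(x)
}

#' Jacobi constant of a CR3BP state
#'
#' \eqn{C = x^2 + y^2 + 2(1-\mu)/r_1 + 2\mu/r_2 - |v|^2}, the conserved
#' energy-like integral of the rotating frame; used to validate the
#' propagation.
#'
#' @param state numeric 6-vector `(x, y, z, vx, vy, vz)`.
#' @param mu mass ratio.
#' @return scalar.
#' @export
jacobi_constant <- function(state, mu) {
  r1 <- sqrt((state[1] + mu)^2 + state[2]^2 + state[3]^2)
  r2 <- sqrt((state[1] - 1 + mu)^2 + state[2]^2 + state[3]^2)
  if ((mu < 1 && r1 == 0) || (mu > 0 && r2 == 0))
    stop("state lies on a primary; Jacobi undefined")
  pot1 <- if (mu < 1) 2 * (1 - mu) / r1 else 0
  pot2 <- if (mu > 0) 2 * mu / r2 else 0
  state[1]^2 + state[2]^2 + pot1 + pot2 - sum(state[4:6]^2)
}

#' Perturb an initial state multiplicatively
#'
#' Each nonzero component is multiplied by `1 + eps` with `eps` drawn
#' uniformly from `(-fraction, +fraction)`; zero components stay exactly
#' zero. Uses the current R random stream.
#'
#' @param state0 numeric 6-vector.
#' @param fraction maximum relative perturbation (default 1%).
#' @return perturbed 6-vector.
#' @export
perturb_initial <- function(state0, fraction = 0.01) {
  stopifnot(fraction >= 0)
  eps <- runif(length(state0), -fraction, fraction)
  ifelse(state0 != 0, state0 * (1 + eps), state0)
}

#' Split a trajectory into washout, train and test segments
#'
#' @param traj a `cr3bp_trajectory`.
#' @param washout_len,train_len,test_len segment lengths in samples; must
#'   sum to at most the trajectory length.
#' @return list of three position matrices `washout`, `train`, `test`
#'   (contiguous, ordered, non-overlapping) plus `index` ranges.
#' @export
split_trajectory <- function(traj, washout_len = 500, train_len = 6500,
                             test_len = 3000) {
  T <- nrow(traj$positions)
  stopifnot(washout_len >= 0, train_len >= 1, test_len >= 1)
  if (washout_len + train_len + test_len > T)
    stop("requested segment lengths (", washout_len + train_len + test_len,
         ") exceed trajectory length (", T, ")")
  w <- seq_len(washout_len)
  tr <- washout_len + seq_len(train_len)
  te <- washout_len + train_len + seq_len(test_len)
  list(washout = traj$positions[w, , drop = FALSE],
       train = traj$positions[tr, , drop = FALSE],
       test = traj$positions[te, , drop = FALSE],
       index = list(washout = w, train = tr, test = te))
}
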