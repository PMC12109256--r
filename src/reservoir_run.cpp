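// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Leaky-tanh reservoir recurrence:
//   x_n = (1 - alpha) * x_{n-1} + alpha * tanh(W x_{n-1} + Win [1; u_n])
// W sparse N x N, Win N x 4 (bias column first), inputs T x 3.
// Returns the N x T matrix of states x_1 .. x_T.
// [[Rcpp::export]]
arma::mat cpp_run_reservoir(const arma::sp_mat& W, const arma::mat& Win,
                            const arma::mat& inputs, double alpha,
                            const arma::vec& x0) {
  const arma::uword N = W.n_rows, T = inputs.n_rows;
  if (W.n_cols != N) Rcpp::stop("W must be square");
  if (Win.n_rows != N || Win.n_cols != 4)
    Rcpp::stop("Win must be N x 4 (bias + three coordinates)");
  if (inputs.n_cols != 3) Rcpp::stop("inputs must have three columns");
  if (x0.n_elem != N) Rcpp::stop("x0 length must match N");
  arma::mat states(N, T);
  arma::vec x = x0;
  arma::vec u(4);
  u(0) = 1.0;
  for (arma::uword n = 0; n < T; ++n) {
    u(1) = inputs(n, 0); u(2) = inputs(n, 1); u(3) = inputs(n, 2);
    x = (1.0 - alpha) * x + alpha * arma::tanh(W * x + Win * u);
    states.col(n) = x;
  }
  return states;
}
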