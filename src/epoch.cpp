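// Compiled inner loops: the per-epoch forward-Euler integration of the
// coupled field/learning dynamics, and the nearest-codebook distortion.
//
// The lateral convolution exploits that a Gaussian of Euclidean distance
// separates across axes: cell * sum_{r'} K e^{-|r-r'|^2/2s^2} g(r') equals
// G A G' with G the one-dimensional Toeplitz factor sqrt(K) * h *
// exp(-(x_i - x_j)^2 / 2 s^2). This reproduces the zero-padded linear
// convolution exactly (same finite sum, reassociated).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List run_epoch_cpp(arma::mat u, arma::mat W, arma::vec p,
                         const arma::mat& Ge, const arma::mat& Gi,
                         double dt, double tau, double gamma, int steps,
                         double blowup_limit) {
  const uword n = u.n_rows, k = W.n_rows;
  const double m = static_cast<double>(W.n_cols);
  const rowvec pt = p.t();

  mat A = clamp(u, 0.0, datum::inf);     // rect(u)
  mat Ce = Ge * A * Ge;                  // excitatory drive, reused across steps
  bool ok = true;
  int fail_step = -1;

  for (int s = 0; s < steps; ++s) {
    // input drive from the current codebook: I = 1 - |W - p|_1 / m
    vec drive = 1.0 - sum(abs(W.each_row() - pt), 1) / m;
    mat I = reshape(drive, n, n);

    mat Ci = Gi * A * Gi;
    u += (dt / tau) * (-u + (Ce - Ci) + I);

    if (!u.is_finite() || abs(u).max() > blowup_limit) {
      ok = false;
      fail_step = s + 1;
      break;
    }

    A = clamp(u, 0.0, datum::inf);
    Ce = Ge * A * Ge;                    // gate for learning at the new field

    mat pull = repmat(pt, k, 1) - W;
    pull.each_col() %= vectorise(Ce);
    W += (dt * gamma) * pull;
  }

  return Rcpp::List::create(Rcpp::Named("u") = u,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("ok") = ok,
                            Rcpp::Named("step") = fail_step);
}

// [[Rcpp::export]]
double distortion_cpp(const arma::mat& X, const arma::mat& W) {
  const uword n = X.n_rows, k = W.n_rows, m = X.n_cols;
  double acc = 0.0;
  for (uword i = 0; i < n; ++i) {
    double best = datum::inf;
    for (uword j = 0; j < k; ++j) {
      double d = 0.0;
      for (uword c = 0; c < m; ++c) {
        const double diff = X(i, c) - W(j, c);
        d += diff * diff;
      }
      if (d < best) best = d;
    }
    acc += best;
  }
  return acc / static_cast<double>(n);
}
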