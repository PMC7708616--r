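# Shared fixtures: the two canonical lateral-kernel parameter sets
# (stable: balanced excitation/inhibition; unstable: strong gains),
# and brute-force oracles kept deliberately independent of the package's
# fast paths.

stable_spec <- function() kernel_spec(Ke = 0.90, sigma_e = 0.1,
                                      Ki = 0.86, sigma_i = 1.0)
unstable_spec <- function() kernel_spec(Ke = 3.0, sigma_e = 0.1,
                                        Ki = 2.80, sigma_i = 1.0)
# identical Gaussians cancel: the lateral kernel is exactly zero
balanced_spec <- function() kernel_spec(Ke = 0.7, sigma_e = 0.4,
                                        Ki = 0.7, sigma_i = 0.4)

# O(k^2) quadrature of the lateral interaction integral, node by node.
naive_convolve <- function(g, spec, grid, which = "lateral") {
  wfun <- if (which == "lateral") {
    function(x) lateral_weight(x, spec)
  } else {
    function(x) gaussian_weight(x, spec$Ke, spec$sigma_e)
  }
  gv <- as.vector(g)
  out <- vapply(seq_len(grid$k), function(t) {
    d <- sqrt(rowSums((grid$nodes - matrix(grid$nodes[t, ], grid$k,
                                           grid$q, byrow = TRUE))^2))
    sum(wfun(d) * gv) * grid$cell_measure
  }, numeric(1))
  if (is.matrix(g)) matrix(out, grid$n, grid$n) else out
}

# Exact integral of an offset Gaussian over the unit square, via Erf.
gaussian_square_integral <- function(center, K, sigma) {
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  axis <- function(c0) {
    sigma * sqrt(pi / 2) *
      (erf((1 - c0) / (sigma * sqrt(2))) + erf(c0 / (sigma * sqrt(2))))
  }
  K * axis(center[1]) * axis(center[2])
}
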