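# High-precision Gauss error function via the exact identity with the
# normal CDF: Erf(x) = 2*Phi(x*sqrt(2)) - 1.
erf_precise <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Rational approximation of the Gauss error function
#'
#' The classical fourth-degree rational approximation
#' \eqn{\mathrm{Erf}(x) \approx 1 - (1 + a_1 x + a_2 x^2 + a_3 x^3 +
#' a_4 x^4)^{-4}} for \eqn{x \ge 0}, extended to negative arguments as an
#' odd function. Absolute error below \eqn{5 \times 10^{-4}}. Provided as a
#' cross-check variant; the default Erf everywhere else is the exact
#' normal-CDF identity.
#'
#' @param x Numeric vector.
#' @return Approximate Erf values in `(-1, 1)`.
#' @export
erf_rational <- function(x) {
  a1 <- 0.278393; a2 <- 0.230389; a3 <- 0.000972; a4 <- 0.078108
  ax <- abs(x)
  val <- 1 - 1 / (1 + a1 * ax + a2 * ax^2 + a3 * ax^3 + a4 * ax^4)^4
  sign(x) * val
}

#' Squared Gaussian self-overlap integral
#'
#' The building block of the closed-form stability condition:
#' \deqn{\xi_{a,b}(\sigma) = \Big( 2\sigma^2 \big(e^{-(a-b)^2/2\sigma^2} - 1\big)
#'   + \sigma \sqrt{2\pi}\,(a-b)\,\mathrm{Erf}\big(\tfrac{a-b}{\sigma\sqrt 2}\big)
#'   \Big)^2,}
#' whose square root equals the double integral
#' \eqn{\int_a^b \int_a^b e^{-(x-y)^2/2\sigma^2}\,dx\,dy}.
#'
#' @param a,b Interval bounds, `b >= a`.
#' @param sigma Gaussian width, strictly positive (vectorized).
#' @param erf Which Erf to use: `"precise"` (normal-CDF identity) or
#'   `"rational"` ([erf_rational()], cross-check mode).
#' @return \eqn{\xi_{a,b}(\sigma)}, non-negative.
#' @examples
#' sqrt(xi_ab(0, 1, 1))  # overlap of a unit-width Gaussian on [0,1]^2
#' @export
xi_ab <- function(a, b, sigma, erf = c("precise", "rational")) {
  erf <- match.arg(erf)
  if (any(sigma <= 0)) stop("`sigma` must be strictly positive")
  if (b < a) stop("`b` must be >= `a`")
  erf_fn <- if (erf == "precise") erf_precise else erf_rational
  d <- a - b
  (2 * sigma^2 * (exp(-d^2 / (2 * sigma^2)) - 1) +
     sigma * sqrt(2 * pi) * d * erf_fn(d / (sigma * sqrt(2))))^2
}

#' Closed-form stability condition left-hand side
#'
#' Evaluates \eqn{K_e^2 \xi_{a,b}(\sigma_e/\sqrt 2) + K_i^2
#' \xi_{a,b}(\sigma_i/\sqrt 2) - 2 K_e K_i \xi_{a,b}\!\big(\sigma_e
#' \sigma_i / \sqrt{\sigma_e^2 + \sigma_i^2}\big)}, the squared L2 norm of
#' the difference-of-Gaussians lateral kernel over the square domain
#' \eqn{[a,b]^2}. Local exponential stability of the map equilibrium is
#' guaranteed when the value is below 1. For `q = 1` the same combination is
#' formed with \eqn{\sqrt{\xi}} in place of \eqn{\xi}.
#'
#' @param spec A [kernel_spec()].
#' @param a,b Domain bounds (default unit square).
#' @param q Domain dimension, 1 or 2.
#' @param erf Passed to [xi_ab()].
#' @return The left-hand side value (a squared L2 norm, non-negative up to
#'   the Erf approximation used).
#' @examples
#' condition_lhs_closed(kernel_spec(0.90, 0.1, 0.86, 1.0))  # stable: < 1
#' condition_lhs_closed(kernel_spec(3.0, 0.1, 2.80, 1.0))   # unstable: > 1
#' @export
condition_lhs_closed <- function(spec, a = 0, b = 1, q = 2,
                                 erf = c("precise", "rational")) {
  stopifnot(inherits(spec, "nfsom_kernel_spec"))
  if (b <= a) stop("`b` must be > `a`")
  if (!q %in% c(1L, 2L)) stop("`q` must be 1 or 2")
  erf <- match.arg(erf)
  pw <- q / 2  # xi is the squared 1-D integral; q-D overlap is xi^(q/2)
  sig_x <- spec$sigma_e * spec$sigma_i / sqrt(spec$sigma_e^2 + spec$sigma_i^2)
  spec$Ke^2 * xi_ab(a, b, spec$sigma_e / sqrt(2), erf)^pw +
    spec$Ki^2 * xi_ab(a, b, spec$sigma_i / sqrt(2), erf)^pw -
    2 * spec$Ke * spec$Ki * xi_ab(a, b, sig_x, erf)^pw
}

#' Stability condition left-hand side by grid quadrature
#'
#' Approximates \eqn{\int_\Omega \int_\Omega w_l(|r - r'|)^2\,dr'\,dr} by a
#' cell-measure-squared weighted sum over all ordered node pairs of the
#' lattice. The sum is accumulated by displacement multiplicity, so the cost
#' is quadratic in the per-side node count rather than in the pair count.
#' Always non-negative (the integrand is a square).
#'
#' @param spec A [kernel_spec()].
#' @param grid A [spatial_grid()].
#' @return Non-negative quadrature value; converges to
#'   [condition_lhs_closed()] as the grid refines.
#' @export
condition_lhs_quadrature <- function(spec, grid) {
  stopifnot(inherits(spec, "nfsom_kernel_spec"), inherits(grid, "nfsom_grid"))
  n <- grid$n
  d <- 0:(n - 1L)
  cnt <- (n - d) * ifelse(d == 0L, 1, 2)  # signed displacements per axis
  if (grid$q == 1L) {
    w2 <- lateral_weight(d * grid$h, spec)^2
    sum(cnt * w2) * grid$cell_measure^2
  } else {
    dist <- grid$h * sqrt(outer(d^2, d^2, "+"))
    w2 <- matrix(lateral_weight(as.vector(dist), spec)^2, n, n)
    sum(outer(cnt, cnt) * w2) * grid$cell_measure^2
  }
}

#' L2 norm of a lateral kernel over the domain
#'
#' Computes \eqn{\bar w_l = \sqrt{\int_\Omega \int_\Omega w(r, r')^2
#' \,dr'\,dr}}, the quantity bounded by \eqn{1/\ell_l} in the general
#' stability condition. For a [kernel_spec()] (distance kernel) this is the
#' square root of [condition_lhs_quadrature()]; an arbitrary two-argument
#' kernel function `w(r, rp)` of coordinate vectors is handled by dense
#' quadrature over all node pairs.
#'
#' @param w A [kernel_spec()] or a function of two coordinate vectors.
#' @param grid A [spatial_grid()] defining the quadrature.
#' @return The non-negative kernel L2 norm.
#' @export
lateral_l2_norm <- function(w, grid) {
  stopifnot(inherits(grid, "nfsom_grid"))
  if (inherits(w, "nfsom_kernel_spec"))
    return(sqrt(condition_lhs_quadrature(w, grid)))
  if (!is.function(w)) stop("`w` must be a kernel_spec or a function(r, rp)")
  nodes <- grid$nodes
  k <- grid$k
  acc <- 0
  for (i in seq_len(k)) {
    ri <- nodes[i, ]
    vals <- vapply(seq_len(k), function(j) w(ri, nodes[j, ]), numeric(1))
    acc <- acc + sum(vals^2)
  }
  sqrt(acc * grid$cell_measure^2)
}

#' Sufficient-excitation condition at the equilibrium
#'
#' Evaluates \eqn{\inf_{r} \int_\Omega w_e(|r - r'|) f_e(u^*(r'))\,dr'} on
#' the lattice (the infimum over the continuous domain is approximated by
#' the minimum over nodes). Positivity means the equilibrium field keeps
#' the learning gate open everywhere, the second hypothesis of the
#' stability theorem.
#'
#' @param u_star Equilibrium field from [equilibrium_field()].
#' @param excit_kernel_table Excitatory kernel table.
#' @param grid The [spatial_grid()].
#' @param f_e Gate activation (default [rect()]).
#' @return A list with `inf_value` and logical `ok`.
#' @export
check_condition10 <- function(u_star, excit_kernel_table, grid, f_e = rect) {
  v <- lateral_convolve(f_e(u_star), excit_kernel_table, grid)
  inf_value <- min(v)
  list(inf_value = inf_value, ok = inf_value > 0)
}

#' Assemble a stability report
#'
#' Evaluates every ingredient of the stability analysis for a given kernel
#' and domain: the closed-form condition value, its grid quadrature, the
#' kernel L2 norm against `1 / ell_l`, and the sufficient-excitation
#' condition at the computed equilibrium. The verdict is `"stable"` when
#' both conditions hold, `"not_guaranteed"` when the norm condition fails
#' (the theorem is only sufficient), and `"undetermined"` when the
#' equilibrium solver does not converge.
#'
#' @param spec A [kernel_spec()].
#' @param grid A [spatial_grid()].
#' @param ell_l Lipschitz constant of the lateral activation (1 for rect).
#' @param f_l,f_e Activations used for the equilibrium and gate.
#' @return An object of class `nfsom_stability_report`.
#' @examples
#' stability_report(kernel_spec(0.90, 0.1, 0.86, 1.0), spatial_grid(16))
#' @export
stability_report <- function(spec, grid, ell_l = 1, f_l = rect, f_e = rect) {
  stopifnot(inherits(spec, "nfsom_kernel_spec"), inherits(grid, "nfsom_grid"))
  lhs_closed <- if (grid$q == 2L)
    condition_lhs_closed(spec, grid$a, grid$b, q = 2L)
  else condition_lhs_closed(spec, grid$a, grid$b, q = 1L)
  lhs_quadrature <- condition_lhs_quadrature(spec, grid)
  wbar_l <- sqrt(lhs_quadrature)
  cond9_ok <- wbar_l < 1 / ell_l

  lat <- kernel_on_grid(spec, grid, "lateral")
  exc <- kernel_on_grid(spec, grid, "excitatory")
  cond10_inf <- NA_real_
  cond10_ok <- NA
  equilibrium_residual <- NA_real_
  verdict <- "undetermined"
  ustar <- tryCatch(
    withCallingHandlers(
      equilibrium_field(lat, grid, f_l = f_l, ell_l = ell_l),
      warning = function(w) invokeRestart("muffleWarning")
    ),
    nfsom_no_convergence = function(e) NULL
  )
  if (!is.null(ustar)) {
    equilibrium_residual <- attr(ustar, "residual")
    c10 <- check_condition10(ustar, exc, grid, f_e = f_e)
    cond10_inf <- c10$inf_value
    cond10_ok <- c10$ok
    verdict <- if (cond9_ok && cond10_ok) "stable" else "not_guaranteed"
  } else if (!cond9_ok) {
    # no contraction and no equilibrium found: stability certainly not shown
    verdict <- "not_guaranteed"
  }

  structure(
    list(lhs_closed = lhs_closed, lhs_quadrature = lhs_quadrature,
         wbar_l = wbar_l, cond9_ok = cond9_ok,
         cond10_inf = cond10_inf, cond10_ok = cond10_ok,
         equilibrium_residual = equilibrium_residual,
         verdict = verdict, spec = spec,
         domain = c(a = grid$a, b = grid$b, q = grid$q, n = grid$n)),
    class = "nfsom_stability_report"
  )
}

#' @export
print.nfsom_stability_report <- function(x, ...) {
  cat("<nfsom_stability_report>\n")
  cat(sprintf("  kernel: Ke = %g (sigma_e = %g), Ki = %g (sigma_i = %g) on [%g, %g]^%d\n",
              x$spec$Ke, x$spec$sigma_e, x$spec$Ki, x$spec$sigma_i,
              x$domain["a"], x$domain["b"], x$domain["q"]))
  cat(sprintf("  condition LHS: closed form %.4f | %dx%d quadrature %.4f (< 1 required)\n",
              x$lhs_closed, x$domain["n"], x$domain["n"], x$lhs_quadrature))
  cat(sprintf("  kernel L2 norm: %.4f (condition: < 1/ell_l) -> %s\n",
              x$wbar_l, if (isTRUE(x$cond9_ok)) "ok" else "violated"))
  cat(sprintf("  excitation at equilibrium: inf = %s -> %s\n",
              format(x$cond10_inf, digits = 4),
              if (isTRUE(x$cond10_ok)) "ok" else if (isFALSE(x$cond10_ok)) "violated" else "unknown"))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}
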