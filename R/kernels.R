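#' Gaussian synaptic weight profile
#'
#' Evaluates \eqn{K e^{-x^2 / 2\sigma^2}} at distance `x`. This is the shape
#' of both the excitatory and the inhibitory lateral kernels.
#'
#' @param x Distance(s), non-negative.
#' @param K Amplitude.
#' @param sigma Width, strictly positive.
#' @return Numeric vector of weights, same length as `x`.
#' @examples
#' gaussian_weight(0, K = 0.9, sigma = 0.1)  # 0.9
#' @export
gaussian_weight <- function(x, K, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single strictly positive number")
  if (any(x < 0)) stop("`x` must be a non-negative distance")
  K * exp(-x^2 / (2 * sigma^2))
}

#' Difference-of-Gaussians lateral weight
#'
#' The lateral coupling is the excitatory Gaussian minus the inhibitory one,
#' \eqn{w_l(x) = w_e(x) - w_i(x)}.
#'
#' @param x Distance(s), non-negative.
#' @param spec A [kernel_spec()].
#' @return Numeric vector of lateral weights.
#' @export
lateral_weight <- function(x, spec) {
  stopifnot(inherits(spec, "nfsom_kernel_spec"))
  gaussian_weight(x, spec$Ke, spec$sigma_e) -
    gaussian_weight(x, spec$Ki, spec$sigma_i)
}

#' Discretized kernel table over lattice displacements
#'
#' Tabulates a distance kernel at every displacement between lattice nodes,
#' as needed for linear (zero-padded, non-circular) convolution over the
#' compact domain. For `q = 1` the table is a vector of length `2n - 1`
#' indexed by displacements `-(n-1) .. (n-1)`; for `q = 2` it is a
#' `(2n-1) x (2n-1)` matrix with the zero displacement at the center.
#'
#' @param spec A [kernel_spec()].
#' @param grid A [spatial_grid()].
#' @param which `"lateral"` for the difference of Gaussians or
#'   `"excitatory"` for the excitatory Gaussian alone.
#' @return An object of class `nfsom_kernel_table` with elements `table`,
#'   `which`, `n`, `q`, `h`, `center` and `spec`.
#' @export
kernel_on_grid <- function(spec, grid, which = c("lateral", "excitatory")) {
  stopifnot(inherits(spec, "nfsom_kernel_spec"), inherits(grid, "nfsom_grid"))
  which <- match.arg(which)
  n <- grid$n
  d <- (-(n - 1L)):(n - 1L)
  wfun <- switch(which,
    lateral = function(x) lateral_weight(x, spec),
    excitatory = function(x) gaussian_weight(x, spec$Ke, spec$sigma_e)
  )
  tab <- if (grid$q == 1L) {
    wfun(abs(d) * grid$h)
  } else {
    wfun(grid$h * sqrt(outer(d^2, d^2, "+")))
  }
  structure(
    list(table = tab, which = which, n = n, q = grid$q, h = grid$h,
         center = n, spec = spec),
    class = "nfsom_kernel_table"
  )
}

# Zero-padded linear convolution of `g` with a displacement table via FFT.
# Returns the same shape as `g`. Lengths are padded to >= 3n - 2 so the
# circular convolution theorem reproduces the linear sum exactly.
fft_convolve <- function(g, tab, n, q) {
  if (q == 1L) {
    L <- stats::nextn(3L * n - 2L)
    gp <- c(g, numeric(L - n))
    kp <- c(tab, numeric(L - (2L * n - 1L)))
    full <- Re(stats::fft(stats::fft(gp) * stats::fft(kp), inverse = TRUE)) / L
    full[n:(2L * n - 1L)]
  } else {
    L <- stats::nextn(3L * n - 2L)
    gp <- matrix(0, L, L); gp[1:n, 1:n] <- g
    kp <- matrix(0, L, L); kp[1:(2L * n - 1L), 1:(2L * n - 1L)] <- tab
    full <- Re(stats::fft(stats::fft(gp) * stats::fft(kp), inverse = TRUE)) / L^2
    full[n:(2L * n - 1L), n:(2L * n - 1L)]
  }
}

#' Lateral interaction integral as a fast convolution
#'
#' Approximates \eqn{\int_\Omega w(|r - r'|)\, g(r')\, dr'} at every lattice
#' node by the cell-measure-weighted node sum
#' \eqn{h^q \sum_{r'} w(|r - r'|) g(r')}, evaluated as a zero-padded FFT
#' convolution. Padding is linear, not circular: the integral runs over the
#' compact domain only, and wrap-around would inject spurious coupling
#' between opposite edges of the sheet.
#'
#' @param g Field values on the grid: a length-`n` vector (`q = 1`), an
#'   `n x n` matrix (`q = 2`), or a length-`n^2` vector which is reshaped
#'   column-major.
#' @param kernel_table A table from [kernel_on_grid()].
#' @param grid The matching [spatial_grid()].
#' @return The convolved field, in the same shape as `g` was supplied.
#' @export
lateral_convolve <- function(g, kernel_table, grid) {
  stopifnot(inherits(kernel_table, "nfsom_kernel_table"),
            inherits(grid, "nfsom_grid"))
  if (kernel_table$n != grid$n || kernel_table$q != grid$q)
    stop("kernel table was built for a different grid")
  n <- grid$n
  reshaped <- FALSE
  if (grid$q == 2L && is.null(dim(g))) {
    if (length(g) != grid$k)
      stop("`g` has length ", length(g), " but the grid has ", grid$k, " nodes")
    g <- matrix(g, n, n)
    reshaped <- TRUE
  }
  if (grid$q == 1L) {
    if (length(g) != n) stop("`g` must have one value per grid node")
  } else if (!all(dim(g) == c(n, n))) {
    stop("`g` must be an ", n, " x ", n, " matrix")
  }
  out <- grid$cell_measure * fft_convolve(g, kernel_table$table, n, grid$q)
  if (reshaped) as.vector(out) else out
}
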