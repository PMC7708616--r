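#' Uniform discretization of the spatial domain
#'
#' Builds the regular lattice used to discretize the cortical sheet
#' \eqn{\Omega = [a, b]^q}. Nodes sit at \eqn{a + i (b - a)/n} per side for
#' \eqn{i = 1, \dots, n} (for the unit square at \eqn{n = 40} this is the
#' lattice \eqn{\cup_{i,j=1}^{40} (i/40, j/40)}), and integrals over
#' \eqn{\Omega} are approximated by node sums weighted by the cell measure
#' \eqn{((b - a)/n)^q}.
#'
#' @param n Number of nodes per side (positive integer).
#' @param a,b Domain bounds, `b >= a`.
#' @param q Domain dimension, 1 or 2.
#'
#' @return An object of class `nfsom_grid`: a list with elements `a`, `b`,
#'   `n`, `q`, `h` (node spacing), `nodes1` (per-side coordinates),
#'   `nodes` (a `k x q` matrix of node coordinates, column-major over the
#'   lattice), `k` (total node count `n^q`) and `cell_measure`.
#' @examples
#' g <- spatial_grid(40)
#' g$cell_measure  # (1/40)^2
#' @export
spatial_grid <- function(n, a = 0, b = 1, q = 2) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a single positive integer")
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L)
    stop("`a` and `b` must be single numbers")
  if (b < a) stop("`b` must be >= `a`")
  if (!q %in% c(1L, 2L)) stop("`q` must be 1 or 2")
  n <- as.integer(n)
  q <- as.integer(q)
  h <- (b - a) / n
  nodes1 <- a + seq_len(n) * h
  nodes <- if (q == 1L) {
    matrix(nodes1, ncol = 1L)
  } else {
    # column-major pairing: node t = (i, j) with t = i + (j - 1) n
    cbind(rep(nodes1, times = n), rep(nodes1, each = n))
  }
  structure(
    list(a = a, b = b, n = n, q = q, h = h, nodes1 = nodes1,
         nodes = nodes, k = n^q, cell_measure = h^q),
    class = "nfsom_grid"
  )
}

#' @export
print.nfsom_grid <- function(x, ...) {
  cat(sprintf("<nfsom_grid> [%g, %g]^%d, %d nodes/side (k = %d), cell measure %g\n",
              x$a, x$b, x$q, x$n, x$k, x$cell_measure))
  invisible(x)
}

#' Lateral connectivity parameters
#'
#' Bundles the amplitudes and widths of the excitatory and inhibitory
#' Gaussian kernels whose difference forms the lateral coupling
#' \eqn{w_l(x) = K_e e^{-x^2/2\sigma_e^2} - K_i e^{-x^2/2\sigma_i^2}}.
#' With \eqn{\sigma_e < \sigma_i} this is the classical Mexican-hat profile.
#'
#' @param Ke,Ki Excitatory / inhibitory amplitudes (strictly positive).
#' @param sigma_e,sigma_i Excitatory / inhibitory widths (strictly positive).
#' @return An object of class `nfsom_kernel_spec`.
#' @examples
#' kernel_spec(Ke = 0.90, sigma_e = 0.1, Ki = 0.86, sigma_i = 1.0)
#' @export
kernel_spec <- function(Ke, sigma_e, Ki, sigma_i) {
  vals <- c(Ke = Ke, sigma_e = sigma_e, Ki = Ki, sigma_i = sigma_i)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals)))
    stop("all kernel parameters must be finite numbers")
  bad <- names(vals)[vals <= 0]
  if (length(bad))
    stop("kernel parameters must be strictly positive: ",
         paste(bad, collapse = ", "))
  structure(list(Ke = Ke, sigma_e = sigma_e, Ki = Ki, sigma_i = sigma_i),
            class = "nfsom_kernel_spec")
}

#' @export
print.nfsom_kernel_spec <- function(x, ...) {
  cat(sprintf("<nfsom_kernel_spec> Ke = %g (sigma_e = %g), Ki = %g (sigma_i = %g)\n",
              x$Ke, x$sigma_e, x$Ki, x$sigma_i))
  invisible(x)
}
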