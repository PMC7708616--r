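#' Quantization distortion of a codebook
#'
#' Mean, over the sample set, of the squared Euclidean distance from each
#' sample to its nearest codebook vector — the vector-quantization loss
#' \eqn{\mathcal{D} = \frac1n \sum_i \min_j |s_i(p) - w_f^j|^2}. Low values
#' mean the map reconstructs the input distribution with little loss.
#'
#' @param samples `n x m` matrix of input samples (rows), or a length-`m`
#'   vector for a single sample.
#' @param codebook `k x m` codebook matrix.
#' @return A single non-negative number.
#' @examples
#' distortion(rbind(c(0, 0), c(1, 0)), rbind(c(0, 0)))  # 0.5
#' @export
distortion <- function(samples, codebook) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(codebook)) stop("`codebook` must be a k x m matrix")
  if (nrow(samples) < 1L) stop("`samples` must contain at least one sample")
  if (ncol(samples) != ncol(codebook))
    stop("samples and codebook dimension mismatch: m = ", ncol(samples),
         " vs ", ncol(codebook))
  distortion_cpp(samples, codebook)
}

#' Pairwise-distance cloud of a map
#'
#' For every unordered node pair the cloud pairs the Euclidean distance
#' between the two codebook vectors (`dx`) with the distance between the
#' corresponding lattice nodes of the input-space discretization (`dy`).
#' A well-formed topographic map makes `dx` roughly proportional to `dy`.
#'
#' @param codebook `k x m` codebook matrix, rows aligned with `grid$nodes`.
#' @param grid The [spatial_grid()].
#' @return An object of class `nfsom_dxdy`: list with `dx`, `dy` (each of
#'   length `k (k - 1) / 2`) and `k`.
#' @export
dxdy_cloud <- function(codebook, grid) {
  stopifnot(inherits(grid, "nfsom_grid"))
  if (!is.matrix(codebook) || nrow(codebook) != grid$k)
    stop("`codebook` must have one row per grid node (k = ", grid$k, ")")
  if (grid$k < 2L) stop("at least two nodes are needed for a distance cloud")
  structure(
    list(dx = as.vector(stats::dist(codebook)),
         dy = as.vector(stats::dist(grid$nodes)),
         k = grid$k),
    class = "nfsom_dxdy"
  )
}

#' Reference line slope of the distance cloud
#'
#' Slope of the straight line through the origin and the cloud centroid,
#' `mean(dx) / mean(dy)`. This is the line the cloud should hug when the
#' map preserves the input topology.
#'
#' @param cloud An [dxdy_cloud()] object.
#' @return The slope (1 for a perfect identity map).
#' @export
reference_slope <- function(cloud) {
  stopifnot(inherits(cloud, "nfsom_dxdy"))
  my <- mean(cloud$dy)
  if (my <= 0) stop("degenerate cloud: all node distances are zero")
  mean(cloud$dx) / my
}

#' No-intercept regression slope of the distance cloud
#'
#' Least-squares slope of `dx` on `dy` constrained through the origin,
#' `sum(dx * dy) / sum(dy^2)`.
#'
#' @param cloud An [dxdy_cloud()] object.
#' @return The fitted slope.
#' @export
regression_slope <- function(cloud) {
  stopifnot(inherits(cloud, "nfsom_dxdy"))
  s2 <- sum(cloud$dy^2)
  if (s2 <= 0) stop("degenerate cloud: all node distances are zero")
  sum(cloud$dx * cloud$dy) / s2
}

#' Topographic performance index
#'
#' Root-mean-square gap between the reference line (origin through the
#' cloud centroid) and the no-intercept regression line, both evaluated at
#' `k_eval` abscissae evenly spaced on `[0, max(dy)]`:
#' \eqn{\mathcal{P} = \sqrt{\tfrac1k \sum_i (a_i - b_i)^2} =
#' |s_{\mathrm{ref}} - s_{\mathrm{fit}}| \sqrt{\tfrac1k \sum_i x_i^2}}.
#' Near zero for a well-formed map. Averaging (rather than summing) over
#' the abscissae makes the index independent of how many evaluation points
#' are used, so values are comparable across lattice sizes; the gap is
#' still dominated by the largest node distances.
#'
#' @param slope_ref Reference slope from [reference_slope()].
#' @param slope_fit Regression slope from [regression_slope()].
#' @param cloud The [dxdy_cloud()] the slopes were computed from.
#' @param k_eval Number of evaluation abscissae (default: the node count).
#' @return A single non-negative number.
#' @export
performance_index <- function(slope_ref, slope_fit, cloud, k_eval = NULL) {
  stopifnot(inherits(cloud, "nfsom_dxdy"),
            is.finite(slope_ref), is.finite(slope_fit))
  if (is.null(k_eval)) k_eval <- cloud$k
  if (k_eval < 1L) stop("`k_eval` must be a positive integer")
  x <- seq(0, max(cloud$dy), length.out = k_eval)
  abs(slope_ref - slope_fit) * sqrt(mean(x^2))
}

#' Map quality summary
#'
#' Convenience wrapper computing the distance cloud, both slopes and the
#' performance index of a trained codebook in one call.
#'
#' @param codebook `k x m` codebook matrix.
#' @param grid The [spatial_grid()].
#' @param k_eval Passed to [performance_index()].
#' @return A list with `slope_ref`, `slope_fit`, `P` and the `cloud`.
#' @export
map_quality <- function(codebook, grid, k_eval = NULL) {
  cloud <- dxdy_cloud(codebook, grid)
  sr <- reference_slope(cloud)
  sf <- regression_slope(cloud)
  list(slope_ref = sr, slope_fit = sf,
       P = performance_index(sr, sf, cloud, k_eval),
       cloud = cloud)
}
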