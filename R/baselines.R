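#' Euclidean distance between equal-length trajectories
#'
#' The flat L2 distance treating each trajectory as one long vector: square
#' root of the sum over all time indices and coordinates of squared
#' differences. Requires equal lengths and equal dimensions. For 1-D series
#' this compares the raw value sequences, not the `(t, y)` embedding.
#'
#' @param a,b trajectories with identical shape (n x d).
#' @return nonnegative scalar.
#' @export
euclidean_distance <- function(a, b) {
  pa <- as_points(a); pb <- as_points(b)
  if (nrow(pa) != nrow(pb) || ncol(pa) != ncol(pb)) {
    abort_input("Euclidean distance needs equal lengths and dimensions")
  }
  sqrt(sum((pa - pb)^2))
}

#' Unconstrained dynamic time warping distance
#'
#' Minimal cumulative sum of Euclidean point-to-point costs over monotone
#' warping paths from (1, 1) to (n, m) with steps (1, 0), (0, 1), (1, 1) —
#' no window, no step weights. The O(n * m) dynamic program runs in compiled
#' code and reports the number of cell updates it performed, which feeds the
#' linear-versus-quadratic scaling comparison against the closed-form
#' distance. DTW is not a metric: it is symmetric with zero self-distance
#' but does not satisfy the triangle inequality.
#'
#' @param a,b trajectories of equal dimension (any lengths).
#' @return nonnegative scalar; attribute `"ops"` holds the cell-update count.
#' @export
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2))  # 1
dtw_distance <- function(a, b) {
  pa <- as_points(a); pb <- as_points(b)
  if (ncol(pa) != ncol(pb)) {
    abort_input("DTW needs trajectories of equal dimension")
  }
  res <- dtw_dp(pa, pb)
  ops_bump(res$ops)
  structure(res$distance, ops = res$ops)
}
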