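#' Local distribution of distances at an anchor point
#'
#' Distribution of intrinsic (polygonal arc-length) distances from one anchor
#' point of the trajectory to every point: `values[k]` is the arc length
#' between points `anchor` and `k` along the curve. With `anchor = 1` this is
#' exactly the distance-from-start profile; other anchors feed the Third
#' Lower Bound. Unlike the start profile, these vectors are generally not
#' monotone.
#'
#' @param traj trajectory (matrix, data frame or numeric vector).
#' @param anchor anchor index, `1 <= anchor <= n`.
#' @return list with `anchor`, `values` (length n, `values[anchor] = 0`) and
#'   uniform `weights`.
#' @export
local_distance_distribution <- function(traj, anchor = 1L) {
  pts <- as_points(traj)
  n <- nrow(pts)
  anchor <- as.integer(anchor)
  if (is.na(anchor) || anchor < 1L || anchor > n) {
    abort_input("`anchor` must be an index between 1 and n")
  }
  cum <- c(0, cumsum(segment_lengths(pts)))
  list(anchor = anchor, values = abs(cum - cum[anchor]),
       weights = rep(1 / n, n))
}

# exact transport linear program via the simplex method (boot::simplex);
# one marginal constraint is redundant (masses both sum to 1) and is dropped
# so the equality system has full rank
transport_lp <- function(cost, mu, nu) {
  n <- length(mu); m <- length(nu)
  if (abs(sum(mu) - 1) > 1e-9 || abs(sum(nu) - 1) > 1e-9) {
    abort_input("marginals must each sum to 1 (within 1e-9)")
  }
  if (n == 1L || m == 1L) {
    # single row/column: the coupling is forced
    return(list(value = sum(outer(mu, nu) * cost),
                plan = outer(mu, nu)))
  }
  nv <- n * m
  A3 <- matrix(0, n + m - 1L, nv)
  for (i in seq_len(n)) A3[i, ((i - 1L) * m + 1L):(i * m)] <- 1
  for (j in seq_len(m - 1L)) A3[n + j, seq(j, nv, by = m)] <- 1
  b3 <- c(mu, nu[-m])
  s <- boot::simplex(a = as.vector(t(cost)), A3 = A3, b3 = b3, maxi = FALSE)
  if (s$solved != 1) {
    abort("transport linear program did not converge",
          class = "gwtau_computational_error")
  }
  list(value = unname(s$value), plan = matrix(s$soln, n, m, byrow = TRUE))
}

#' Exact 1-D Wasserstein distance by linear programming
#'
#' Brute-force validation oracle: solves the transport linear program with
#' cost `|z_i - w_j|^p` over all couplings of the two weighted supports and
#' returns the p-th root of the optimum. Intended for small instances
#' (`n * m` up to about 1e4); the closed-form [wasserstein_1d()] must agree
#' with it to solver precision.
#'
#' @param z_values,w_values numeric supports (any order).
#' @param z_weights,w_weights probability weights (sum to 1 within 1e-9).
#' @param p transport exponent, `p >= 1`.
#' @return the exact p-Wasserstein distance.
#' @export
wasserstein_1d_lp_oracle <- function(z_values, z_weights, w_values, w_weights,
                                     p = 2) {
  if (p < 1) abort_input("`p` must be >= 1")
  cost <- abs(outer(z_values, w_values, "-"))^p
  transport_lp(cost, z_weights, w_weights)$value^(1 / p)
}

#' Third Lower Bound (TLB) on the Gromov-Wasserstein distance
#'
#' Polynomially computable lower bound built from local distributions of
#' distances: the cost of matching point `i` of one trajectory to point `j`
#' of the other is the 1-D Wasserstein-p distance between their local
#' distance distributions (computed by the closed form on sorted values —
#' local distributions are not monotone, so this validator sorts, unlike the
#' fast start-profile path), and the bound is half the p-th root of the
#' optimal transport cost between the uniform point measures under that
#' matching cost. Sits below both the full Gromov-Wasserstein distance and
#' the GW-tau upper surrogate: `TLB <= GW <= GW_tau`.
#'
#' @param a,b trajectories (matrices, data frames or numeric vectors).
#' @param p transport exponent (default 2).
#' @return nonnegative scalar bound.
#' @export
tlb <- function(a, b, p = 2) {
  pa <- as_points(a); pb <- as_points(b)
  n <- nrow(pa); m <- nrow(pb)
  cum_a <- c(0, cumsum(segment_lengths(pa)))
  cum_b <- c(0, cumsum(segment_lengths(pb)))
  # sorted local distance distributions at every anchor
  loc_a <- lapply(seq_len(n), function(i) sort(abs(cum_a - cum_a[i])))
  loc_b <- lapply(seq_len(m), function(j) sort(abs(cum_b - cum_b[j])))
  C <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      C[i, j] <- wasserstein_1d(distance_profile(loc_a[[i]]),
                                distance_profile(loc_b[[j]]), p = p)
    }
  }
  res <- transport_lp(C^p, rep(1 / n, n), rep(1 / m, m))
  0.5 * res$value^(1 / p)
}

#' Pairwise TLB matrix for a dataset
#'
#' @inheritParams gw_tau_matrix
#' @return a [dist_matrix()] with `metric = "tlb"`.
#' @export
tlb_matrix <- function(data, p = 2, embed_time_for_1d = TRUE) {
  trj <- trajectories(data, embed_time_for_1d = embed_time_for_1d)
  if (length(trj) < 2L) abort_input("need at least 2 trajectories")
  if (anyDuplicated(names(trj))) abort_input("duplicate trajectory ids")
  K <- length(trj)
  D <- matrix(0, K, K, dimnames = list(names(trj), names(trj)))
  for (i in seq_len(K - 1L)) {
    for (j in seq((i + 1L), K)) {
      D[i, j] <- D[j, i] <- tlb(trj[[i]], trj[[j]], p = p)
    }
  }
  dist_matrix(D, metric = "tlb", p = p, labels = dataset_labels(data))
}
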