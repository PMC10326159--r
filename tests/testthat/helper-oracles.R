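# shared fixtures and independent oracles built in code

# random nondecreasing profile starting at 0 (like a cumulative arc length)
rand_profile <- function(n) {
  distance_profile(c(0, cumsum(stats::rexp(n - 1L))))
}

# random trajectory in d dimensions
rand_traj <- function(n, d = 2L) {
  matrix(stats::rnorm(n * d), n, d)
}

# exhaustive DTW: enumerate every monotone warping path from (1,1) to (n,m)
# with steps (1,0), (0,1), (1,1); exponential, for tiny inputs only
dtw_enumerate <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    c0 <- cost(i, j)
    if (i == n && j == m) return(c0)
    opts <- c()
    if (i < n) opts <- c(opts, rec(i + 1L, j))
    if (j < m) opts <- c(opts, rec(i, j + 1L))
    if (i < n && j < m) opts <- c(opts, rec(i + 1L, j + 1L))
    c0 + min(opts)
  }
  rec(1L, 1L)
}

# quantile-coupling mass via explicit CDF-interval intersections
coupling_by_intervals <- function(n, m) {
  lam <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      lo <- max((i - 1) / n, (j - 1) / m)
      hi <- min(i / n, j / m)
      lam[i, j] <- max(0, hi - lo)
    }
  }
  lam
}

# rigid motion: random rotation (any d), translation, optional reflection
rigid_motion <- function(pts, reflect = FALSE) {
  d <- ncol(pts)
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))), d)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  if (reflect) Q[, 1L] <- -Q[, 1L]
  shift <- stats::rnorm(d, sd = 3)
  sweep(pts %*% t(Q), 2L, -shift)
}

half_amplitude <- function(y) (max(y) - min(y)) / 2
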