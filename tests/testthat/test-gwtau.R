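test_that("gw_tau matches worked examples across dimensions", {
  a <- rbind(c(0, 0), c(1, 0)); b <- rbind(c(0, 0), c(3, 0))
  expect_equal(gw_tau(a, b, p = 2), sqrt(2))
  expect_equal(gw_tau(a, a), 0)
  line2d <- cbind(0:2, 0)
  line3d <- cbind(0:2, 0, 0)
  expect_equal(gw_tau(line2d, line3d), 0)  # same arc-length law, different d
})

test_that("gw_tau satisfies metric axioms on profile space", {
  set.seed(77)
  for (rep in 1:40) {
    a <- rand_traj(sample(2:12, 1), sample(1:3, 1))
    b <- rand_traj(sample(2:12, 1), sample(1:3, 1))
    cc <- rand_traj(sample(2:12, 1), sample(1:3, 1))
    p <- sample(c(1, 2), 1)
    dab <- gw_tau(a, b, p); dba <- gw_tau(b, a, p)
    expect_identical(dab, dba)      # exact symmetry
    expect_gte(dab, 0)
    expect_equal(gw_tau(a, a, p), 0)
    dac <- gw_tau(a, cc, p); dcb <- gw_tau(cc, b, p)
    expect_lte(dab, dac + dcb + 1e-10)
  }
})

test_that("gw_tau is invariant under rigid motions", {
  set.seed(13)
  for (rep in 1:20) {
    pts <- rand_traj(sample(2:20, 1), sample(2:3, 1))
    moved <- rigid_motion(pts, reflect = sample(c(TRUE, FALSE), 1))
    expect_lt(gw_tau(pts, moved), 1e-9)
  }
})

test_that("mirror images are indistinguishable (pseudo-metric, by design)", {
  set.seed(3)
  pts <- rand_traj(10, 2)
  mirror <- pts %*% diag(c(-1, 1))
  expect_lt(gw_tau(pts, mirror), 1e-12)
})

test_that("coordinate scaling obeys the |s - 1| law", {
  set.seed(8)
  for (s in c(0.25, 0.5, 1.5, 2, 4)) {
    pts <- rand_traj(12, 3)
    z <- cumulative_arclength(pts)$values
    for (p in c(1, 2)) {
      expected <- abs(s - 1) * (mean(z^p))^(1 / p)
      expect_equal(gw_tau(pts, s * pts, p), expected, tolerance = 1e-12)
    }
  }
  # monotone in |s - 1|
  pts <- rand_traj(9, 2)
  d_vals <- vapply(c(1, 1.2, 1.5, 2, 3), function(s) gw_tau(pts, s * pts),
                   numeric(1))
  expect_true(all(diff(d_vals) > 0))
})

test_that("single-point trajectories give the p-mean of the other profile", {
  pts <- rbind(c(0, 0), c(3, 4), c(3, 9))
  z <- cumulative_arclength(pts)$values
  single <- matrix(c(5, 5), 1)
  for (p in c(1, 2, 3)) {
    expect_equal(gw_tau(single, pts, p), (mean(z^p))^(1 / p))
  }
})

test_that("gw_tau_matrix fills symmetric matrices with zero diagonal", {
  d <- trajectory_tbl(list(a = cbind(0:3, 0), b = rbind(c(0, 0), c(2, 0)),
                           cc = rand_traj(5, 2)))
  M <- gw_tau_matrix(d)
  expect_s3_class(M, "dist_matrix")
  expect_equal(M$D, t(M$D))
  expect_equal(diag(M$D), setNames(rep(0, 3), M$ids))
  expect_equal(M$D["a", "b"],
               gw_tau(cbind(0:3, 0), rbind(c(0, 0), c(2, 0))))
  # identical trajectories give an all-zero matrix
  same <- trajectory_tbl(list(x = cbind(0:3, 0), y = cbind(0:3, 0)))
  expect_equal(max(gw_tau_matrix(same)$D), 0)
  # duplicate ids rejected
  dup <- dplyr::bind_rows(d, d)
  expect_error(gw_tau_matrix(dup), class = "gwtau_input_error")
})

test_that("tidy/glance on distance matrices return well-formed tibbles", {
  d <- trajectory_tbl(list(a = cbind(0:3, 0), b = rbind(c(0, 0), c(2, 0)),
                           cc = cbind(0:4, 1)))
  M <- gw_tau_matrix(d)
  td <- tidy(M)
  expect_equal(nrow(td), 3)           # K choose 2 unordered pairs
  expect_named(td, c("id_1", "id_2", "distance"))
  g <- glance(M)
  expect_equal(g$n_trajectories, 3)
  expect_equal(g$metric, "gwtau")
})
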