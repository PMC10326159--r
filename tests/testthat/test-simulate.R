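test_that("generators are pure functions of their configuration", {
  expect_identical(sim_analytic_shapes(seed = 4), sim_analytic_shapes(seed = 4))
  expect_identical(sim_straight_around(n_per_class = 3, n_points = 50,
                                       excursion_window = 10, seed = 9),
                   sim_straight_around(n_per_class = 3, n_points = 50,
                                       excursion_window = 10, seed = 9))
  expect_identical(sim_wobble(seed = 2), sim_wobble(seed = 2))
  expect_identical(
    sim_lotka_volterra(n_per_class = 2, n_points = 50, seed = 3),
    sim_lotka_volterra(n_per_class = 2, n_points = 50, seed = 3))
  expect_false(identical(sim_wobble(seed = 2), sim_wobble(seed = 3)))
})

test_that("analytic shapes are unit-speed with the expected similarity blocks", {
  d <- sim_analytic_shapes(n_line = 60, n_circle = 240, spacing = "uniform",
                           seed = 0)
  trj <- trajectories(d)
  spans <- c(helix_3d = 23 * pi / 12, circle_2d = 23 * pi / 12,
             line_3d = 2, line_2d = 2)
  for (nm in names(spans)) {
    tot <- max(cumulative_arclength(trj[[nm]])$values)
    expect_lt(abs(tot - spans[[nm]]), 1e-3)
  }
  # within-type distances below all between-type distances (default sampling)
  M <- gw_tau_matrix(sim_analytic_shapes(seed = 0))$D
  within <- c(M["helix_3d", "circle_2d"], M["line_3d", "line_2d"])
  between <- c(M["helix_3d", "line_3d"], M["helix_3d", "line_2d"],
               M["circle_2d", "line_3d"], M["circle_2d", "line_2d"])
  expect_lt(max(within), min(between))
})

test_that("StraightAround honours its contract and noise-free limit", {
  d <- sim_straight_around(n_per_class = 4, n_points = 60,
                           excursion_window = 10, seed = 1)
  expect_equal(dplyr::n_distinct(d$trajectory_id), 8L)
  expect_equal(nrow(d), 8L * 60L)
  expect_equal(sort(unique(d$label)), c(1, 2))
  trj <- trajectories(d)
  expect_true(all(vapply(trj, ncol, integer(1)) == 3L))
  # vanishing noise: straight segments from (1,1,1) to the origin
  tiny <- sim_straight_around(n_per_class = 1, n_points = 40,
                              base_noise_sd = 1e-12, excursion_sd = 1e-11,
                              excursion_window = 10, seed = 2)
  m <- trajectories(tiny)[[1]]
  s <- seq(0, 1, length.out = 40)
  expect_lt(max(abs(m - cbind(1 - s, 1 - s, 1 - s))), 1e-9)
  expect_error(sim_straight_around(base_noise_sd = 0.2, excursion_sd = 0.1),
               class = "gwtau_input_error")
})

test_that("Lotka-Volterra regimes realize the advertised local behaviour", {
  regs <- lv_regimes()
  eig_interior <- function(reg) eigen(reg$A)$values  # Jacobian at (1,1,1)
  e1 <- eig_interior(regs$stable_focus)
  expect_true(all(Re(e1) < 0))
  expect_true(any(Im(e1) != 0))
  e2 <- eig_interior(regs$unstable_focus)
  expect_true(any(Re(e2) > 0 & Im(e2) != 0))
  # origin Jacobian is diag(r): positive growth rates = unstable node
  expect_true(all(regs$unstable_node$r > 0))
  expect_true(all(abs(Im(eigen(diag(regs$unstable_node$r))$values)) == 0))
})

test_that("Lotka-Volterra trajectories stay positive and converge as labelled", {
  d <- sim_lotka_volterra(n_per_class = 3, n_points = 200, seed = 5)
  trj <- trajectories(d)
  expect_true(all(vapply(trj, min, numeric(1)) > 0))
  # class 1 (stable focus): end point closer to (1,1,1) than the start
  for (r in 1:3) {
    x <- trj[[sprintf("class1_%02d", r)]]
    d_start <- sqrt(sum((x[1, ] - 1)^2))
    d_end <- sqrt(sum((x[nrow(x), ] - 1)^2))
    expect_lt(d_end, d_start * 0.1)
  }
  # class 2 (unstable focus): moves away from (1,1,1)
  for (r in 1:3) {
    x <- trj[[sprintf("class2_%02d", r)]]
    expect_gt(max(sqrt(rowSums((x - 1)^2))), 10 * sqrt(sum((x[1, ] - 1)^2)))
  }
  # class 3 (unstable node at 0): leaves the origin's neighbourhood
  for (r in 1:3) {
    x <- trj[[sprintf("class3_%02d", r)]]
    expect_gt(sqrt(sum(x[nrow(x), ]^2)), 5 * sqrt(sum(x[1, ]^2)))
  }
})

test_that("random rotations preserve gw_tau and labels, scramble Euclidean", {
  d <- sim_lotka_volterra(n_per_class = 3, n_points = 100, seed = 7)
  rot <- random_rotate(d, per_trajectory = TRUE, seed = 11)
  expect_identical(dataset_labels(d), dataset_labels(rot))
  M <- gw_tau_matrix(d)$D; Mr <- gw_tau_matrix(rot)$D
  expect_lt(max(abs(M - Mr)), 1e-9)
  # a trajectory and its rotated copy are gw_tau-indistinguishable
  trj <- trajectories(d); trj_r <- trajectories(rot)
  expect_lt(gw_tau(trj[[1]], trj_r[[1]]), 1e-9)
  # per-trajectory rotation changes coordinate-based distances
  E <- trajectory_dist(d, "euclidean")$D
  Er <- trajectory_dist(rot, "euclidean")$D
  expect_gt(max(abs(E - Er)), 1e-3)
  # shared rotation is reproducible and 2-D input is rejected
  expect_identical(random_rotate(d, per_trajectory = FALSE, seed = 1),
                   random_rotate(d, per_trajectory = FALSE, seed = 1))
  d2 <- trajectory_tbl(list(a = cbind(0:3, 0)))
  expect_error(random_rotate(d2), class = "gwtau_input_error")
})

test_that("wobble dataset has the printed sizes and phase-averaging damping", {
  w <- sim_wobble(seed = 0)
  labs <- dataset_labels(w)
  expect_equal(unname(table(labs)[c("flat", "osc1", "osc2")]),
               c(10L, 12L, 7L), ignore_attr = TRUE)
  counts <- dplyr::count(w, trajectory_id)
  expect_true(all(counts$n == 40L))
  expect_equal(sort(unique(w$t)), (0:39) * 5)
  # pointwise mean of the phase-jittered class is damped below the class
  # average amplitude
  osc1 <- dplyr::filter(w, label == "osc1")
  m <- mean_trajectory(osc1)
  class_amp <- mean(vapply(split(osc1$dim_1, osc1$trajectory_id),
                           half_amplitude, numeric(1)))
  expect_lt(half_amplitude(m$dim_1), class_amp)
})
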