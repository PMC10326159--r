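#' Four analytic shapes in different dimensions
#'
#' A miniature dataset of four unit-speed curves used to illustrate
#' cross-dimensional comparison: a 3-D helix `(cos t, sin t, t)/sqrt(2)` and
#' a 2-D circle `(cos t, sin t)` on unequally spaced points in
#' `[0, 23*pi/12]`, and a 3-D line `(t, t, t)/sqrt(3)` and 2-D line
#' `(t, t)/sqrt(2)` on unequally spaced points in `[0, 2]`. All four have
#' unit speed, so the final cumulative arc length approximates the interval
#' length; shapes of the same kind (the two lines; helix vs circle) end up
#' close in GW-tau despite living in different dimensions.
#'
#' @param n_line points per line (default 30).
#' @param n_circle points per circular shape (default 48).
#' @param spacing `"random"` (sorted uniform draws including both endpoints)
#'   or `"uniform"`.
#' @param seed integer seed.
#' @return long tibble with labels `"circular"` / `"line"`.
#' @export
sim_analytic_shapes <- function(n_line = 30, n_circle = 48,
                                spacing = c("random", "uniform"), seed = 0L) {
  spacing <- match.arg(spacing)
  if (n_line < 2 || n_circle < 2) abort_input("need at least 2 points per shape")
  withr::with_seed(seed, {
    grid <- function(n, a, b) {
      if (spacing == "uniform") seq(a, b, length.out = n)
      else c(a, sort(stats::runif(n - 2L, a, b)), b)
    }
    tc <- grid(n_circle, 0, 23 * pi / 12)
    tl <- grid(n_line, 0, 2)
    mats <- list(
      helix_3d  = cbind(cos(tc), sin(tc), tc) / sqrt(2),
      circle_2d = cbind(cos(tc), sin(tc)),
      line_3d   = cbind(tl, tl, tl) / sqrt(3),
      line_2d   = cbind(tl, tl) / sqrt(2)
    )
    trajectory_tbl(mats,
                   times = list(tc, tc, tl, tl),
                   labels = c("circular", "circular", "line", "line"))
  })
}

#' StraightAround: straight 3-D descent with an early or late excursion
#'
#' Two classes of noisy 3-D series on a common time grid: every trajectory
#' runs in a straight line from (1, 1, 1) to the origin with small Gaussian
#' coordinate noise; on top, a window of higher-variance Gaussian excursion
#' is placed in the first third of the path (class 1) or the last third
#' (class 2). The classes differ only in *when* the burst of activity
#' happens, the regime where distribution-of-distance comparison shines and
#' warping-based alignment struggles.
#'
#' @param n_per_class trajectories per class (default 30).
#' @param n_points points per trajectory (default 300).
#' @param base_noise_sd baseline Gaussian noise sd per coordinate (default 0.01).
#' @param excursion_sd excursion noise sd per coordinate (default 0.15).
#' @param excursion_window consecutive points carrying the excursion
#'   (default 60).
#' @param seed integer seed.
#' @return long tibble with integer labels 1 / 2; generator settings are
#'   attached as attribute `"config"`.
#' @export
sim_straight_around <- function(n_per_class = 30, n_points = 300,
                                base_noise_sd = 0.01, excursion_sd = 0.15,
                                excursion_window = 60, seed = 0L) {
  if (!(excursion_sd > base_noise_sd && base_noise_sd > 0)) {
    abort_input("need excursion_sd > base_noise_sd > 0")
  }
  third <- floor(n_points / 3)
  if (excursion_window > third) {
    abort_input("`excursion_window` must fit inside a third of the path")
  }
  withr::with_seed(seed, {
    s <- seq(0, 1, length.out = n_points)
    base <- cbind(1 - s, 1 - s, 1 - s)
    mats <- list(); labels <- integer(0)
    for (cls in 1:2) {
      for (r in seq_len(n_per_class)) {
        pts <- base + matrix(stats::rnorm(n_points * 3, 0, base_noise_sd),
                             n_points, 3)
        lo <- if (cls == 1L) 1L else n_points - third + 1L
        start <- lo + sample.int(third - excursion_window + 1L, 1L) - 1L
        win <- start:(start + excursion_window - 1L)
        pts[win, ] <- pts[win, ] +
          matrix(stats::rnorm(excursion_window * 3, 0, excursion_sd),
                 excursion_window, 3)
        mats[[sprintf("class%d_%02d", cls, r)]] <- pts
        labels <- c(labels, cls)
      }
    }
    out <- trajectory_tbl(mats, times = rep(list(s), length(mats)),
                          labels = labels)
    attr(out, "config") <- list(n_per_class = n_per_class,
                                n_points = n_points,
                                base_noise_sd = base_noise_sd,
                                excursion_sd = excursion_sd,
                                excursion_window = excursion_window,
                                seed = seed)
    out
  })
}

#' Default 3-D Lotka-Volterra regimes
#'
#' Three parameterizations of the competitive Lotka-Volterra system
#' `dx/dt = diag(x) (r + A x)` with circulant interaction matrix
#' `A = -(c) * circ(1, alpha, beta)` and `r = -A %*% 1`, which places an
#' interior equilibrium at (1, 1, 1). The Jacobian there is `A` itself, with
#' eigenvalues `-c (1 + alpha + beta)` (real) and
#' `-c (1 - (alpha + beta)/2) +- i c sqrt(3) (beta - alpha) / 2`:
#'
#' * `stable_focus`: `alpha + beta < 2`, `alpha != beta` — spiral into
#'   (1, 1, 1); trajectories start in a wide box around the equilibrium.
#' * `unstable_focus`: `alpha + beta > 2` — spiral out of (1, 1, 1) toward
#'   large sustained oscillations; trajectories start close to it.
#' * `unstable_node`: `r > 0` makes the origin an unstable node (Jacobian
#'   `diag(r)`); trajectories start near the origin and grow away from it.
#'
#' Each regime carries an initial-condition sampling rule — a uniformly
#' random direction at fixed radius `ic_radius` from `ic_center` (restricted
#' to the positive orthant when the center sits on the boundary, as for the
#' origin regime) — and an integration horizon `t_max`. Fixing the radius
#' keeps escape / relaxation times, and hence total arc lengths, coherent
#' within a class.
#'
#' @return named list of regime configurations, one per class.
#' @export
lv_regimes <- function() {
  circ <- function(a, b, cc) rbind(c(a, b, cc), c(cc, a, b), c(b, cc, a))
  make <- function(alpha, beta, ic_center, ic_radius, ic_positive, t_max) {
    A <- -circ(1, alpha, beta)
    list(A = A, r = as.numeric(-A %*% rep(1, 3)),
         ic_center = ic_center, ic_radius = ic_radius,
         ic_positive = ic_positive, t_max = t_max)
  }
  list(
    stable_focus   = make(0.5, 0.8, ic_center = c(1, 1, 1), ic_radius = 0.35,
                          ic_positive = FALSE, t_max = 40),
    unstable_focus = c(make(0.8, 1.4, ic_center = c(1, 1, 1), ic_radius = 0.05,
                            ic_positive = FALSE, t_max = 40),
                       # perturb inside the unstable eigenplane (orthogonal to
                       # the stable (1,1,1) eigendirection of the circulant
                       # Jacobian), so every draw actually exhibits the
                       # spiral-out behavior that defines the class instead of
                       # sliding down the stable manifold
                       list(ic_plane_normal = c(1, 1, 1) / sqrt(3))),
    unstable_node  = make(0.5, 0.5, ic_center = c(0, 0, 0), ic_radius = 0.10,
                          ic_positive = TRUE, t_max = 40)
  )
}

lv_sample_ic <- function(reg) {
  u <- stats::rnorm(3)
  if (reg$ic_positive) u <- abs(u)
  if (!is.null(reg$ic_plane_normal)) {
    nrm <- reg$ic_plane_normal / sqrt(sum(reg$ic_plane_normal^2))
    u <- u - sum(u * nrm) * nrm
  }
  reg$ic_center + reg$ic_radius * u / sqrt(sum(u^2))
}

lv_rhs_log <- function(t, logx, parms) {
  x <- exp(logx)
  list(as.numeric(parms$r + parms$A %*% x))
}

#' Simulated 3-D Lotka-Volterra trajectories in three dynamical regimes
#'
#' Integrates `dx/dt = diag(x)(r + A x)` for the three regimes of
#' [lv_regimes()] (stable focus at (1, 1, 1), unstable focus at (1, 1, 1),
#' unstable node at the origin), each from seeded random initial conditions,
#' on a fixed output grid. Integration is performed in log-coordinates
#' (`d log x / dt = r + A x`), so all coordinates stay strictly positive —
#' the positive orthant is invariant for Lotka-Volterra dynamics and the
#' transform enforces that exactly. Runs that blow up or fail are retried
#' with fresh initial conditions up to `max_retry` times.
#'
#' @param n_per_class trajectories per class (default 20).
#' @param n_points output grid size per trajectory (default 1000).
#' @param regimes list of regime configurations, default [lv_regimes()];
#'   custom `(A, r)` parameterizations may be supplied in the same format.
#' @param seed integer seed.
#' @param max_retry retries per trajectory on integration failure.
#' @return long tibble with labels 1, 2, 3 (regime order).
#' @export
sim_lotka_volterra <- function(n_per_class = 20, n_points = 1000,
                               regimes = lv_regimes(), seed = 0L,
                               max_retry = 5L) {
  withr::with_seed(seed, {
    mats <- list(); labels <- integer(0)
    for (cls in seq_along(regimes)) {
      reg <- regimes[[cls]]
      times <- seq(0, reg$t_max, length.out = n_points)
      for (r in seq_len(n_per_class)) {
        pts <- NULL
        for (try in seq_len(max_retry)) {
          ic <- lv_sample_ic(reg)
          sol <- try(deSolve::ode(y = log(ic), times = times,
                                  func = lv_rhs_log,
                                  parms = list(r = reg$r, A = reg$A),
                                  method = "lsoda"), silent = TRUE)
          if (!inherits(sol, "try-error") && nrow(sol) == n_points &&
              all(is.finite(sol[, -1])) && max(sol[, -1]) < log(1e6)) {
            pts <- exp(unname(sol[, -1, drop = FALSE]))
            break
          }
        }
        if (is.null(pts)) {
          abort("Lotka-Volterra integration failed after retries",
                class = "gwtau_computational_error")
        }
        mats[[sprintf("class%d_%02d", cls, r)]] <- pts
        labels <- c(labels, cls)
      }
    }
    trajectory_tbl(mats,
                   times = rep(list(seq(0, 1, length.out = n_points)),
                               length(mats)),
                   labels = labels)
  })
}

haar_rotation <- function(d = 3L) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))), d)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Apply Haar-uniform random 3-D rotations to a dataset
#'
#' Rotates every trajectory by a random rotation matrix drawn uniformly from
#' SO(3) — one shared rotation, or an independent one per trajectory.
#' Rotations are rigid motions, so arc lengths (and hence every GW-tau
#' distance) are unchanged, while coordinate-based distances (Euclidean,
#' DTW) are scrambled under per-trajectory rotation.
#'
#' @param data long-format 3-D dataset.
#' @param per_trajectory independent rotation per trajectory (default TRUE)?
#' @param seed integer seed.
#' @return the rotated dataset, labels preserved.
#' @export
random_rotate <- function(data, per_trajectory = TRUE, seed = 0L) {
  data <- as_trajectory_tbl(data)
  dims <- dim_cols(data)
  if (length(dims) != 3L) abort_input("random_rotate expects 3-D data")
  withr::with_seed(seed, {
    ids <- unique(data$trajectory_id)
    shared <- if (!per_trajectory) haar_rotation(3L)
    for (id in ids) {
      R <- if (per_trajectory) haar_rotation(3L) else shared
      rows <- data$trajectory_id == id
      data[rows, dims] <- as.matrix(data[rows, dims]) %*% t(R)
    }
    data
  })
}

#' Wobble-like 1-D angle series: one flat class, two oscillatory classes
#'
#' Synthetic stand-in for pronuclear "wobble" quantification in early
#' nematode embryos: the measured signal is the angle between the centrosome
#' axis and the embryo's long axis, sampled on a shared grid of `n_points`
#' time points at `dt`-second spacing. The control-like flat class drifts
#' slowly with low-amplitude noise; the two perturbation-like classes
#' oscillate with per-trajectory random amplitude and phase. Phases are
#' jittered uniformly on `(-phase_jitter, phase_jitter)`, which is what
#' makes the pointwise class mean damp the oscillation.
#'
#' @param n_flat flat (control-like) trajectories (default 10).
#' @param n_osc oscillatory trajectories per perturbation class
#'   (default `c(12, 7)`).
#' @param n_points shared grid length (default 40).
#' @param dt sampling interval, seconds (default 5).
#' @param amplitude mean oscillation amplitude, degrees (default 15).
#' @param frequency oscillation frequency, Hz (default 0.03); the second
#'   oscillatory class runs at `1.4 * frequency` with `0.8 * amplitude`.
#' @param phase_jitter half-width of the uniform phase draw, radians
#'   (default `pi`).
#' @param noise_sd additive measurement noise sd, degrees (default 1).
#' @param seed integer seed.
#' @return long tibble of 1-D series with labels `"flat"`, `"osc1"`,
#'   `"osc2"`.
#' @export
sim_wobble <- function(n_flat = 10, n_osc = c(12, 7), n_points = 40, dt = 5,
                       amplitude = 15, frequency = 0.03, phase_jitter = pi,
                       noise_sd = 1, seed = 0L) {
  if (any(c(n_flat, n_osc, n_points, dt, amplitude, frequency, noise_sd) <= 0)) {
    abort_input("all size and scale parameters must be positive")
  }
  withr::with_seed(seed, {
    t <- (seq_len(n_points) - 1L) * dt
    mats <- list(); labels <- character(0)
    for (r in seq_len(n_flat)) {
      drift <- stats::rnorm(1, 0, 0.01)
      y <- drift * t + stats::rnorm(n_points, 0, noise_sd)
      mats[[sprintf("flat_%02d", r)]] <- matrix(y, ncol = 1)
      labels <- c(labels, "flat")
    }
    class_amp <- c(amplitude, 0.8 * amplitude)
    class_freq <- c(frequency, 1.4 * frequency)
    for (cls in seq_along(n_osc)) {
      for (r in seq_len(n_osc[[cls]])) {
        amp <- abs(stats::rnorm(1, class_amp[cls], 0.1 * class_amp[cls]))
        phi <- stats::runif(1, -phase_jitter, phase_jitter)
        y <- amp * sin(2 * pi * class_freq[cls] * t + phi) +
          stats::rnorm(n_points, 0, noise_sd)
        mats[[sprintf("osc%d_%02d", cls, r)]] <- matrix(y, ncol = 1)
        labels <- c(labels, paste0("osc", cls))
      }
    }
    trajectory_tbl(mats, times = rep(list(t), length(mats)), labels = labels)
  })
}
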