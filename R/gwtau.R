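#' GW-tau distance between two trajectories
#'
#' The Gromov-Wasserstein-type distance between two trajectories of possibly
#' different ambient dimensions and lengths: the p-Wasserstein distance
#' between their distance-from-start profiles (the pushforwards of the
#' uniform point measures under cumulative arc length). Because both
#' pushforwards live on the real line with sorted supports, the distance has
#' a closed form — O(N) for equal lengths, O(n + m) coupling terms otherwise.
#'
#' This is a pseudo-metric on trajectories (a true metric on profile space):
#' two trajectories with the same distribution of distances from their start
#' — for example a curve and its mirror image, or any rigid motion of it —
#' are indistinguishable. That invariance is deliberate and is what makes the
#' distance robust to rotations of the ambient space.
#'
#' @param a,b trajectories: n x d numeric matrices (d may differ between the
#'   two), data frames of coordinates, or numeric vectors.
#' @param p transport exponent, `p >= 1` (default 2).
#' @return nonnegative scalar distance.
#' @export
#' @examples
#' a <- rbind(c(0, 0), c(1, 0))
#' b <- rbind(c(0, 0), c(3, 0))
#' gw_tau(a, b)  # sqrt(2): profiles (0, 1) vs (0, 3)
gw_tau <- function(a, b, p = 2) {
  wasserstein_1d(cumulative_arclength(a), cumulative_arclength(b), p = p)
}

#' Pairwise GW-tau distance matrix for a dataset
#'
#' Computes each trajectory's distance-from-start profile once, then fills
#' the upper triangle of the pairwise matrix and mirrors it (the distance is
#' symmetric with a zero diagonal). One-dimensional series are embedded as
#' `(t, y)` plane curves first (see [trajectories()]).
#'
#' @param data long-format trajectory dataset (see [as_trajectory_tbl()]).
#' @param p transport exponent (default 2).
#' @param embed_time_for_1d embed 1-D series as `(t, y)` before profiling.
#' @return a [dist_matrix()] with `metric = "gwtau"`.
#' @export
gw_tau_matrix <- function(data, p = 2, embed_time_for_1d = TRUE) {
  trj <- trajectories(data, embed_time_for_1d = embed_time_for_1d)
  if (length(trj) < 2L) abort_input("need at least 2 trajectories")
  if (anyDuplicated(names(trj))) abort_input("duplicate trajectory ids")
  profs <- lapply(trj, cumulative_arclength)
  K <- length(profs)
  D <- matrix(0, K, K, dimnames = list(names(trj), names(trj)))
  for (i in seq_len(K - 1L)) {
    for (j in seq((i + 1L), K)) {
      D[i, j] <- D[j, i] <- wasserstein_1d(profs[[i]], profs[[j]], p = p)
    }
  }
  dist_matrix(D, metric = "gwtau", p = p, labels = dataset_labels(data))
}

#' Pairwise distance matrix under a chosen trajectory metric
#'
#' One entry point for all metrics used in the workflow: the closed-form
#' GW-tau distance, the Third Lower Bound, and the Euclidean / dynamic time
#' warping baselines. GW-tau and TLB compare 1-D series as `(t, y)` plane
#' curves; Euclidean and DTW compare raw value sequences — the conventional
#' treatment for each family.
#'
#' @param data long-format trajectory dataset.
#' @param metric one of `"gwtau"`, `"tlb"`, `"euclidean"`, `"dtw"`.
#' @param p transport exponent for `"gwtau"` / `"tlb"`.
#' @return a [dist_matrix()].
#' @export
trajectory_dist <- function(data, metric = c("gwtau", "tlb", "euclidean", "dtw"),
                            p = 2) {
  metric <- match.arg(metric)
  if (metric == "gwtau") return(gw_tau_matrix(data, p = p))
  if (metric == "tlb") return(tlb_matrix(data, p = p))
  trj <- trajectories(data, embed_time_for_1d = FALSE)
  if (length(trj) < 2L) abort_input("need at least 2 trajectories")
  if (anyDuplicated(names(trj))) abort_input("duplicate trajectory ids")
  f <- if (metric == "euclidean") euclidean_distance else dtw_distance
  K <- length(trj)
  D <- matrix(0, K, K, dimnames = list(names(trj), names(trj)))
  for (i in seq_len(K - 1L)) {
    for (j in seq((i + 1L), K)) {
      D[i, j] <- D[j, i] <- f(trj[[i]], trj[[j]])
    }
  }
  dist_matrix(D, metric = metric, p = if (metric == "euclidean") 2 else NA_real_,
              labels = dataset_labels(data))
}

#' Symmetric trajectory distance matrix
#'
#' Container for a pairwise distance matrix together with the metric name and
#' exponent. Validates symmetry (within 1e-9), a zero diagonal and
#' nonnegative entries.
#'
#' @param D square numeric matrix with id dimnames.
#' @param metric metric name (`"gwtau"`, `"dtw"`, `"euclidean"`, `"tlb"`).
#' @param p exponent used (NA where not applicable).
#' @param labels optional named vector of class labels per id.
#' @return object of class `dist_matrix`.
#' @export
dist_matrix <- function(D, metric = "gwtau", p = 2, labels = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) abort_input("distance matrix must be square")
  if (is.null(rownames(D))) {
    ids <- paste0("trj_", seq_len(nrow(D)))
    dimnames(D) <- list(ids, ids)
  }
  if (max(abs(D - t(D))) > 1e-9) abort_input("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) abort_input("distance matrix diagonal must be zero")
  if (any(D < 0)) abort_input("distance matrix entries must be nonnegative")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  structure(list(ids = rownames(D), D = D, metric = metric, p = p,
                 labels = labels),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("<dist_matrix> ", length(x$ids), " trajectories, metric = ", x$metric,
      if (!is.na(x$p)) paste0(" (p = ", format(x$p), ")"), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$D

#' @export
as.dist.dist_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$D, diag = diag, upper = upper)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a distance matrix into a long pair table
#'
#' @param x a [dist_matrix()].
#' @param upper_only keep each unordered pair once (default).
#' @param ... unused.
#' @return tibble with columns `id_1`, `id_2`, `distance`.
#' @export
tidy.dist_matrix <- function(x, upper_only = TRUE, ...) {
  out <- tibble::as_tibble(as.data.frame.table(x$D, stringsAsFactors = FALSE))
  names(out) <- c("id_1", "id_2", "distance")
  if (upper_only) {
    idx1 <- match(out$id_1, x$ids)
    idx2 <- match(out$id_2, x$ids)
    out <- out[idx1 < idx2, , drop = FALSE]
  }
  out
}

#' @export
glance.dist_matrix <- function(x, ...) {
  off <- x$D[upper.tri(x$D)]
  tibble::tibble(n_trajectories = length(x$ids), metric = x$metric, p = x$p,
                 min_distance = min(off), median_distance = stats::median(off),
                 max_distance = max(off))
}

#' Heatmap of a trajectory distance matrix
#'
#' @param object a [dist_matrix()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dist_matrix <- function(object, ...) {
  long <- tidy(object, upper_only = FALSE)
  long$id_1 <- factor(long$id_1, levels = object$ids)
  long$id_2 <- factor(long$id_2, levels = rev(object$ids))
  ggplot2::ggplot(long, ggplot2::aes(.data$id_1, .data$id_2,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = object$metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
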