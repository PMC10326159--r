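#' 1-nearest-neighbour classification from a cross-distance table
#'
#' Each test item receives the label of the training item at minimal
#' distance; ties are broken deterministically in favour of the lowest
#' training index (the common archive-benchmark convention).
#'
#' @param cross n_test x n_train matrix or data frame of distances (rows =
#'   test items, columns = training items).
#' @param train_labels labels for the training items (length = n_train).
#' @return tibble with columns `test_id`, `pred_label`.
#' @export
knn1_classify <- function(cross, train_labels) {
  cross <- as.matrix(cross)
  if (ncol(cross) == 0L) abort_input("empty training set")
  if (length(train_labels) != ncol(cross)) {
    abort_input("`train_labels` must have one label per training column")
  }
  idx <- apply(cross, 1L, which.min)
  test_id <- rownames(cross)
  if (is.null(test_id)) test_id <- paste0("test_", seq_len(nrow(cross)))
  tibble::tibble(test_id = test_id, pred_label = train_labels[idx])
}

#' Agglomerative clustering on a precomputed distance matrix
#'
#' @param D a [dist_matrix()] (or plain symmetric matrix).
#' @param k number of clusters to cut at.
#' @param linkage `"single"` or `"complete"`.
#' @return tibble with columns `trajectory_id`, `cluster` (integer).
#' @export
hierarchical_cluster <- function(D, k, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  Dm <- if (inherits(D, "dist_matrix")) D$D else as.matrix(D)
  if (!is.numeric(k) || k < 1 || k > nrow(Dm)) {
    abort_input("`k` must be between 1 and the number of trajectories")
  }
  cl <- cutree(hclust(stats::as.dist(Dm), method = linkage), k = k)
  tibble::tibble(trajectory_id = rownames(Dm), cluster = as.integer(cl))
}

#' k-medoids (PAM) clustering on a precomputed distance matrix
#'
#' Partitioning around medoids on the distance matrix itself, so any metric
#' (including ones without coordinates) can drive it. The PAM BUILD + SWAP
#' search is deterministic given the matrix; the `seed` argument is accepted
#' for interface stability and future stochastic variants.
#'
#' @inheritParams hierarchical_cluster
#' @param seed integer seed (kept for reproducible pipelines).
#' @return tibble with columns `trajectory_id`, `cluster`.
#' @export
kmedoids_cluster <- function(D, k, seed = 0L) {
  Dm <- if (inherits(D, "dist_matrix")) D$D else as.matrix(D)
  if (!is.numeric(k) || k < 1 || k > nrow(Dm)) {
    abort_input("`k` must be between 1 and the number of trajectories")
  }
  if (k == nrow(Dm)) {  # every point its own medoid
    return(tibble::tibble(trajectory_id = rownames(Dm),
                          cluster = seq_len(nrow(Dm))))
  }
  cl <- withr::with_seed(seed,
    cluster::pam(stats::as.dist(Dm), k = k, cluster.only = TRUE))
  tibble::tibble(trajectory_id = rownames(Dm), cluster = as.integer(cl))
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson's classical MDS: double-centre the squared distances and keep
#' the top eigenpairs. Deterministic (no seed); coordinates are unique up to
#' rotation, reflection and sign. Eigenvalues are returned as diagnostics —
#' negative ones measure how far the matrix is from being Euclidean. A
#' non-metric alternative (`flavor = "isoMDS"`, Kruskal stress majorization
#' from MASS) is available for heavily non-Euclidean matrices.
#'
#' @param D a [dist_matrix()] (or plain symmetric matrix).
#' @param dim embedding dimension (default 2; must be `<= K - 1`).
#' @param flavor `"classical"` (default) or `"isoMDS"`.
#' @return object of class `trj_embedding`: tibble `coords`
#'   (`trajectory_id`, `mds_1` ... `mds_dim`), `eigenvalues`, `metric`.
#' @export
mds_embed <- function(D, dim = 2, flavor = c("classical", "isoMDS")) {
  flavor <- match.arg(flavor)
  metric <- if (inherits(D, "dist_matrix")) D$metric else "unknown"
  labels <- if (inherits(D, "dist_matrix")) D$labels else NULL
  Dm <- if (inherits(D, "dist_matrix")) D$D else as.matrix(D)
  K <- nrow(Dm)
  if (dim > K - 1L) abort_input("`dim` must be at most K - 1")
  if (flavor == "classical") {
    # degenerate matrices (fewer positive eigenvalues than dim) are handled
    # by zero-padding below; cmdscale's warning about them is redundant here
    fit <- suppressWarnings(cmdscale(stats::as.dist(Dm), k = dim, eig = TRUE))
    pts <- fit$points
    if (ncol(pts) < dim) {  # degenerate matrices can drop axes; pad with 0
      pts <- cbind(pts, matrix(0, K, dim - ncol(pts)))
    }
    eig <- fit$eig
  } else {
    if (!requireNamespace("MASS", quietly = TRUE)) {
      abort_input("flavor = \"isoMDS\" needs the MASS package")
    }
    eps <- max(Dm) * 1e-9 + 1e-12
    fit <- MASS::isoMDS(stats::as.dist(pmax(Dm, eps) * (1 - diag(K))),
                        k = dim, trace = FALSE)
    pts <- fit$points
    eig <- rep(NA_real_, K)
  }
  coords <- tibble::tibble(trajectory_id = rownames(Dm))
  for (j in seq_len(dim)) coords[[paste0("mds_", j)]] <- pts[, j]
  structure(list(coords = coords, eigenvalues = eig, metric = metric,
                 labels = labels, flavor = flavor),
            class = "trj_embedding")
}

#' @export
print.trj_embedding <- function(x, ...) {
  cat("<trj_embedding> ", nrow(x$coords), " trajectories in ",
      ncol(x$coords) - 1L, "D (", x$flavor, " MDS, metric = ", x$metric,
      ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.trj_embedding <- function(x, ...) {
  out <- x$coords
  if (!is.null(x$labels)) out$label <- unname(x$labels[out$trajectory_id])
  out
}

#' @export
glance.trj_embedding <- function(x, ...) {
  eig <- x$eigenvalues
  pos <- sum(pmax(eig, 0), na.rm = TRUE)
  used <- sum(pmax(head(sort(eig, decreasing = TRUE),
                        ncol(x$coords) - 1L), 0), na.rm = TRUE)
  tibble::tibble(n_trajectories = nrow(x$coords),
                 dim = ncol(x$coords) - 1L,
                 goodness_of_fit = if (pos > 0) used / pos else NA_real_,
                 min_eigenvalue = suppressWarnings(min(eig, na.rm = TRUE)))
}

#' Scatter plot of an MDS embedding
#'
#' @param object a `trj_embedding`.
#' @param ... unused.
#' @return a ggplot object, coloured by label when labels are known.
#' @export
autoplot.trj_embedding <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$mds_1, .data$mds_2))
  if ("label" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$label)),
                                 size = 2) +
      ggplot2::labs(colour = "label")
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = "MDS 1", y = "MDS 2") + ggplot2::theme_minimal()
}

#' k-means clustering of embedded coordinates
#'
#' Lloyd's algorithm with seeded multi-restart on the MDS coordinates.
#'
#' @param emb a `trj_embedding` (or data frame with `trajectory_id` and
#'   coordinate columns).
#' @param k number of clusters.
#' @param seed integer seed; fixed seeds give identical labels across runs.
#' @param nstart random restarts (default 25).
#' @return tibble with columns `trajectory_id`, `cluster`.
#' @export
kmeans_on_embedding <- function(emb, k, seed = 0L, nstart = 25L) {
  coords <- if (inherits(emb, "trj_embedding")) emb$coords else
    tibble::as_tibble(emb)
  X <- as.matrix(coords[setdiff(names(coords), c("trajectory_id", "label"))])
  if (!is.numeric(k) || k < 1 || k > nrow(X)) {
    abort_input("`k` must be between 1 and the number of points")
  }
  km <- withr::with_seed(seed, kmeans(X, centers = k, nstart = nstart))
  tibble::tibble(trajectory_id = coords$trajectory_id,
                 cluster = as.integer(km$cluster))
}

# all one-to-one assignments of predicted clusters onto true classes,
# maximizing matched counts; exhaustive over permutations of the smaller side
best_cluster_matching <- function(tab) {
  n_small <- min(dim(tab))
  if (nrow(tab) <= ncol(tab)) {
    rows_small <- TRUE; small <- seq_len(nrow(tab)); big <- seq_len(ncol(tab))
  } else {
    rows_small <- FALSE; small <- seq_len(ncol(tab)); big <- seq_len(nrow(tab))
  }
  if (length(small) > 8L) {
    abort_input("cluster matching supports at most 8 clusters on one side")
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(rest) c(v[i], rest))
    }), recursive = FALSE)
  }
  best <- 0
  for (assign_big in perms(big)) {
    sel <- assign_big[seq_len(n_small)]
    matched <- sum(vapply(seq_len(n_small), function(s) {
      if (rows_small) tab[small[s], sel[s]] else tab[sel[s], small[s]]
    }, numeric(1)))
    if (matched > best) best <- matched
  }
  best
}

#' Clustering quality against known classes
#'
#' `error_count` is the minimum number of misassigned items over all
#' one-to-one matchings of predicted clusters onto true classes (cluster
#' labels are arbitrary, so the matching is optimized); `ari` is the
#' adjusted Rand index.
#'
#' @param pred_labels,true_labels equal-length label vectors.
#' @return tibble with columns `error_count`, `ari`, `n`.
#' @export
clustering_quality <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) {
    abort_input("label vectors must have equal length")
  }
  tab <- table(pred_labels, true_labels)
  matched <- best_cluster_matching(unclass(tab))
  tibble::tibble(error_count = as.integer(length(pred_labels) - matched),
                 ari = mclust::adjustedRandIndex(pred_labels, true_labels),
                 n = length(pred_labels))
}

#' Pointwise mean trajectory of a group
#'
#' The arithmetic mean of coordinates at each shared time index — the
#' barycenter of the group under 1-D Euclidean distance between y-values.
#' Averaging phase-shifted oscillations this way damps their amplitude, the
#' failure mode [averaging_assessment()] is designed to expose.
#'
#' @param group long-format dataset; all trajectories must share one time
#'   grid and dimension.
#' @param id id given to the mean trajectory.
#' @return a long tibble containing the single mean trajectory.
#' @export
mean_trajectory <- function(group, id = "mean") {
  trj <- trajectories(group, embed_time_for_1d = FALSE)
  if (length(trj) < 1L) abort_input("empty group")
  times <- lapply(trj, attr, "times")
  dims <- vapply(trj, ncol, integer(1))
  if (length(unique(dims)) != 1L ||
      any(!vapply(times, function(ts) isTRUE(all.equal(ts, times[[1L]])),
                  logical(1)))) {
    abort_input("all trajectories must share one time grid and dimension")
  }
  avg <- Reduce(`+`, trj) / length(trj)
  trajectory_tbl(list(m = avg), times = list(times[[1L]]),
                 labels = NULL) |>
    dplyr::mutate(trajectory_id = id)
}

#' Where do candidate average trajectories land among the groups?
#'
#' Joins the labelled data with externally supplied candidate average
#' trajectories (pointwise means, transport barycenters, ...), computes the
#' full GW-tau matrix and its MDS embedding, and reports for every candidate
#' its mean GW-tau distance to each labelled group and the nearest group. A
#' faithful average should land nearest its own group; a shape-destroying
#' one (like the damped pointwise mean of phase-shifted oscillations) drifts
#' toward whichever group its distorted shape resembles.
#'
#' @param data long-format labelled dataset.
#' @param averages long-format dataset of candidate average trajectories
#'   (ids must not clash with `data`).
#' @param p transport exponent (default 2).
#' @return object of class `avg_assessment`: tibble `report` (columns
#'   `average_id`, `group`, `mean_gw_tau`, `nearest`), the `dist_matrix` and
#'   the `trj_embedding` used.
#' @export
averaging_assessment <- function(data, averages, p = 2) {
  data <- as_trajectory_tbl(data)
  if (!"label" %in% names(data)) abort_input("`data` must carry labels")
  averages <- as_trajectory_tbl(averages)
  avg_ids <- unique(averages$trajectory_id)
  if (any(avg_ids %in% unique(data$trajectory_id))) {
    abort_input("average ids must not clash with data ids")
  }
  averages$label <- NA_character_
  combined <- dplyr::bind_rows(
    dplyr::mutate(data, label = as.character(.data$label)), averages)
  D <- gw_tau_matrix(combined, p = p)
  emb <- mds_embed(D)
  labs <- dataset_labels(data)
  groups <- unique(unname(labs))
  report <- purrr::map_dfr(avg_ids, function(aid) {
    by_group <- vapply(groups, function(g) {
      mean(D$D[aid, names(labs)[labs == g]])
    }, numeric(1))
    tibble::tibble(average_id = aid, group = groups,
                   mean_gw_tau = unname(by_group),
                   nearest = by_group == min(by_group))
  })
  structure(list(report = report, dist = D, embedding = emb),
            class = "avg_assessment")
}

#' @export
print.avg_assessment <- function(x, ...) {
  nearest <- x$report[x$report$nearest, c("average_id", "group")]
  cat("<avg_assessment>\n")
  for (i in seq_len(nrow(nearest))) {
    cat("  ", nearest$average_id[i], "-> nearest group:", nearest$group[i], "\n")
  }
  invisible(x)
}

#' @export
tidy.avg_assessment <- function(x, ...) x$report
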