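#' @useDynLib gwtau, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn
#' @importFrom stats cmdscale cutree hclust kmeans sd
#' @importFrom utils head tail
"_PACKAGE"

abort_input <- function(msg, ...) {
  abort(msg, class = "gwtau_input_error", ...)
}

abort_internal <- function(msg, ...) {
  abort(msg, class = "gwtau_internal_error", ...)
}

#' Coerce a single trajectory to a coordinate matrix
#'
#' Accepts an n x d numeric matrix (one row per time point), a data frame of
#' coordinate columns, or a bare numeric vector (taken as a 1-dimensional
#' series). All coordinates must be finite.
#'
#' @param x matrix, data frame or numeric vector of coordinates.
#' @return an n x d numeric matrix.
#' @keywords internal
as_points <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort_input("a trajectory must be a numeric matrix, data frame or vector")
  }
  if (nrow(x) < 1L) abort_input("a trajectory needs at least one point")
  if (!all(is.finite(x))) abort_input("trajectory coordinates must be finite")
  storage.mode(x) <- "double"
  x
}

dim_cols <- function(data) {
  grep("^dim_[0-9]+$", names(data), value = TRUE)
}

#' Validate a long-format trajectory dataset
#'
#' A trajectory dataset is a long tibble with one row per observed time point:
#' columns `trajectory_id`, `t`, `dim_1` ... `dim_k` and optionally `label`.
#' Trajectories of different ambient dimensions may share one table: a
#' 2-D trajectory in a table that also holds 3-D ones simply leaves `dim_3`
#' entirely `NA`. Within each trajectory, the used dimension columns must be
#' contiguous from `dim_1` and fully finite (`NaN` / `Inf` are rejected with
#' row numbers), and `t` must be nondecreasing.
#'
#' @param data a data frame in long format.
#' @return the validated data as a tibble, rows ordered by id then `t`.
#' @export
as_trajectory_tbl <- function(data) {
  if (!is.data.frame(data)) abort_input("`data` must be a data frame")
  data <- tibble::as_tibble(data)
  dims <- dim_cols(data)
  missing <- setdiff(c("trajectory_id", "t"), names(data))
  if (length(missing) > 0 || length(dims) == 0) {
    abort_input(paste0(
      "dataset needs columns trajectory_id, t and dim_1..dim_k; missing: ",
      paste(c(missing, if (length(dims) == 0) "dim_*"), collapse = ", ")
    ))
  }
  dims <- dims[order(as.integer(sub("^dim_", "", dims)))]
  coord <- as.matrix(data[dims])
  bad <- which(apply(coord, 1L, function(r) any(is.nan(r) | is.infinite(r))))
  if (length(bad) > 0) {
    abort_input(paste0("non-finite coordinates at row(s) ",
                       paste(head(bad, 5L), collapse = ", ")))
  }
  data$trajectory_id <- as.character(data$trajectory_id)
  for (id in unique(data$trajectory_id)) {
    sub <- coord[data$trajectory_id == id, , drop = FALSE]
    used <- colSums(is.na(sub)) == 0
    empty <- colSums(is.na(sub)) == nrow(sub)
    if (any(!used & !empty) || !any(used) ||
        !all(used == (cumsum(used) == seq_along(used)))) {
      abort_input(paste0("trajectory ", id, ": dimension columns must be ",
                         "contiguous from dim_1 and either fully observed ",
                         "or fully NA"))
    }
  }
  split_t <- split(data$t, data$trajectory_id)
  non_mono <- names(split_t)[!vapply(split_t, function(ts) !is.unsorted(ts),
                                     logical(1))]
  if (length(non_mono) > 0) {
    abort_input(paste0("time column `t` must be nondecreasing within each ",
                       "trajectory; violated for id(s): ",
                       paste(head(non_mono, 5L), collapse = ", ")))
  }
  dplyr::arrange(data, .data$trajectory_id, .data$t)
}

#' Split a long dataset into per-trajectory coordinate matrices
#'
#' One-dimensional series (a single `dim_1` column) are by convention compared
#' as plane curves `(t, y)`: elapsed time becomes the first coordinate, so the
#' arc-length profile sees both how long the series runs and how much it
#' moves. Set `embed_time_for_1d = FALSE` to keep the raw value sequence
#' (Euclidean and DTW baselines use the raw values).
#'
#' @param data long-format dataset (see [as_trajectory_tbl()]).
#' @param embed_time_for_1d embed 1-D series as `(t, y)` curves?
#' @return named list of coordinate matrices, each carrying `label` and
#'   `times` attributes; order follows first appearance in `data`.
#' @export
trajectories <- function(data, embed_time_for_1d = TRUE) {
  data <- as_trajectory_tbl(data)
  dims <- dim_cols(data)
  ids <- unique(data$trajectory_id)
  out <- lapply(ids, function(id) {
    rows <- data[data$trajectory_id == id, , drop = FALSE]
    pts <- as.matrix(rows[dims])
    pts <- pts[, colSums(is.na(pts)) == 0, drop = FALSE]  # this trajectory's dims
    if (ncol(pts) == 1L && embed_time_for_1d) {
      pts <- cbind(rows$t, pts[, 1L])
    }
    dimnames(pts) <- NULL
    attr(pts, "times") <- rows$t
    if ("label" %in% names(rows)) attr(pts, "label") <- rows$label[[1L]]
    pts
  })
  names(out) <- ids
  out
}

#' Per-trajectory labels of a dataset
#'
#' @param data long-format dataset.
#' @return named vector of labels keyed by trajectory id, or `NULL` when the
#'   dataset carries no `label` column.
#' @export
dataset_labels <- function(data) {
  data <- as_trajectory_tbl(data)
  if (!"label" %in% names(data)) return(NULL)
  lab <- dplyr::distinct(data, .data$trajectory_id, .data$label)
  stats::setNames(lab$label, lab$trajectory_id)
}

#' Build a long-format dataset from coordinate matrices
#'
#' @param mats named list of n x d coordinate matrices (or vectors for 1-D).
#' @param times list of time vectors, or `NULL` for `0, 1, ...` per series.
#' @param labels optional vector of labels, one per trajectory.
#' @return a long tibble with columns `trajectory_id`, `t`, `dim_*`, `label`.
#' @export
trajectory_tbl <- function(mats, times = NULL, labels = NULL) {
  if (is.null(names(mats))) names(mats) <- paste0("trj_", seq_along(mats))
  purrr::map_dfr(seq_along(mats), function(i) {
    m <- as_points(mats[[i]])
    ts <- if (!is.null(times)) times[[i]] else seq_len(nrow(m)) - 1
    out <- tibble::tibble(trajectory_id = names(mats)[[i]], t = as.numeric(ts))
    for (j in seq_len(ncol(m))) out[[paste0("dim_", j)]] <- m[, j]
    if (!is.null(labels)) out$label <- labels[[i]]
    out
  })
}
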