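#' Read a long-format trajectory CSV
#'
#' Expects a header with columns `trajectory_id`, `t`, `dim_1` ... `dim_k`
#' and optionally `label`. Rows are validated (finite coordinates,
#' nondecreasing `t` within each trajectory) with row numbers in error
#' messages.
#'
#' @param path file path.
#' @return a long tibble (see [as_trajectory_tbl()]).
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) abort_input(paste0("no such file: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_trajectory_tbl(data)
}

#' Write a long-format trajectory CSV
#'
#' @param data long-format dataset.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  readr::write_csv(as_trajectory_tbl(data), path)
  invisible(path)
}

#' Read a flat time-series archive file (UCR-style)
#'
#' One series per row: the first field is the class label, the remaining
#' fields the values. Tab or comma delimiters are auto-detected. Series get
#' unit-spaced times `t = 1 ... N`; ragged rows are rejected (archive
#' datasets are fixed length).
#'
#' @param path file path.
#' @return a long tibble of labelled 1-D series.
#' @export
read_ucr <- function(path) {
  if (!file.exists(path)) abort_input(paste0("no such file: ", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  rows <- strsplit(trimws(readLines(path)), delim, fixed = TRUE)
  rows <- rows[lengths(rows) > 0]
  if (length(rows) == 0) abort_input("empty file")
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    abort_input(paste0("ragged rows: row ", which(lens != lens[1])[1],
                       " has ", lens[lens != lens[1]][1], " fields, expected ",
                       lens[1]))
  }
  if (lens[1] < 2L) abort_input("rows need a label plus at least one value")
  mats <- list(); labels <- character(0)
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[i]]))
    if (any(is.na(vals))) {
      abort_input(paste0("non-numeric value in row ", i))
    }
    mats[[sprintf("series_%03d", i)]] <- matrix(vals[-1L], ncol = 1)
    labels <- c(labels, format(vals[1L]))
  }
  n <- lens[1] - 1L
  trajectory_tbl(mats, times = rep(list(seq_len(n)), length(mats)),
                 labels = labels)
}

#' Write a distance matrix to CSV
#'
#' Writes `#`-prefixed header comments carrying the metric name and
#' exponent, then an id header row and one id-labelled row per trajectory at
#' 17 significant digits (lossless double round trip).
#'
#' @param D a [dist_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  if (!inherits(D, "dist_matrix")) abort_input("`D` must be a dist_matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# metric: ", D$metric),
               paste0("# p: ", format(D$p, digits = 17))), con)
  writeLines(paste(c("id", D$ids), collapse = ","), con)
  for (i in seq_along(D$ids)) {
    writeLines(paste(c(D$ids[i], format(D$D[i, ], digits = 17,
                                        scientific = TRUE)),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' Rejects asymmetry beyond 1e-9, negative entries and nonzero diagonals.
#'
#' @param path file path.
#' @return a [dist_matrix()].
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) abort_input(paste0("no such file: ", path))
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  metric <- sub("^# metric:\\s*", "", grep("^# metric:", meta, value = TRUE))
  p_line <- sub("^# p:\\s*", "", grep("^# p:", meta, value = TRUE))
  p <- if (length(p_line) == 1L) suppressWarnings(as.numeric(p_line)) else NA_real_
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  ids <- header[-1L]
  K <- length(ids)
  if (length(body) != K + 1L) abort_input("matrix body has wrong row count")
  D <- matrix(NA_real_, K, K, dimnames = list(ids, ids))
  for (i in seq_len(K)) {
    f <- strsplit(body[i + 1L], ",", fixed = TRUE)[[1L]]
    if (length(f) != K + 1L || f[1L] != ids[i]) {
      abort_input(paste0("malformed matrix row ", i))
    }
    D[i, ] <- as.numeric(f[-1L])
  }
  if (any(!is.finite(D))) abort_input("non-finite distance entries")
  if (max(abs(D - t(D))) > 1e-9) abort_input("matrix asymmetric beyond 1e-9")
  if (any(D < 0)) abort_input("negative distance entries")
  if (any(abs(diag(D)) > 1e-12)) abort_input("nonzero diagonal")
  dist_matrix(D, metric = if (length(metric) == 1L) metric else "unknown", p = p)
}
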