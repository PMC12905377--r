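#' Construct a labelled trace matrix
#'
#' The central container: a cells x frames matrix of dF/F0 values plus a
#' per-cell metadata table and the shared [time_grid()].
#'
#' @param values Numeric matrix, one row per cell, `grid$n_frames` columns.
#' @param meta Data frame with columns `cell_id`, `group`, `animal_id`,
#'   `sex`; one row per cell, aligned with `values`.
#' @param grid A [time_grid()].
#'
#' @return A `trace_matrix` object.
#' @export
trace_matrix <- function(values, meta, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.matrix(values) || !is.numeric(values)) abort("`values` must be a numeric matrix.")
  if (anyNA(values) || any(!is.finite(values))) abort("`values` must contain no missing or non-finite entries.")
  if (ncol(values) != grid$n_frames) {
    abort(sprintf("`values` has %d columns but the grid has %d frames.", ncol(values), grid$n_frames))
  }
  meta <- as_tibble(meta)
  need <- c("cell_id", "group", "animal_id", "sex")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(sprintf("`meta` is missing column(s): %s.", paste(miss, collapse = ", ")))
  if (nrow(meta) != nrow(values)) {
    abort(sprintf("%d trace rows but %d metadata rows.", nrow(values), nrow(meta)))
  }
  if (anyDuplicated(meta$cell_id)) abort("`meta$cell_id` must be unique.")
  rownames(values) <- meta$cell_id
  colnames(values) <- sprintf("f%04d", seq_len(ncol(values)) - 1L)
  structure(list(values = values, meta = meta, grid = grid), class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d cells x %d frames\n", nrow(x$values), ncol(x$values)))
  print(x$grid)
  print(table(x$meta$group))
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

#' Number of cells / frames in a trace matrix
#' @param x A [trace_matrix()].
#' @export
n_cells <- function(x) nrow(as_trace_values(x))

#' @rdname n_cells
#' @export
n_frames <- function(x) ncol(as_trace_values(x))

#' Subset cells of a trace matrix
#'
#' @param x A [trace_matrix()].
#' @param i Row (cell) index vector.
#' @param ... Ignored.
#' @return A [trace_matrix()] with the selected cells.
#' @export
`[.trace_matrix` <- function(x, i, ...) {
  trace_matrix(x$values[i, , drop = FALSE], x$meta[i, , drop = FALSE], x$grid)
}

#' Long (tidy) view of a trace matrix
#'
#' @param x A [trace_matrix()].
#' @return Tibble with columns `cell_id`, `group`, `frame` (0-based),
#'   `time_s`, `df_f0`.
#' @export
trace_tibble <- function(x) {
  stopifnot(inherits(x, "trace_matrix"))
  nf <- ncol(x$values)
  tibble(
    cell_id = rep(x$meta$cell_id, each = nf),
    group = rep(x$meta$group, each = nf),
    frame = rep.int(seq_len(nf) - 1L, nrow(x$values)),
    time_s = rep.int((seq_len(nf) - 1L) / x$grid$rate, nrow(x$values)),
    df_f0 = as.vector(t(x$values))
  )
}

#' Restrict traces to the basal (pre-ligand) window
#'
#' Keeps only frames before ligand onset, mirroring basal-only
#' classification from the first 600 frames (5 min at 2 Hz). The returned
#' grid has an empty ligand window, so a second truncation is rejected.
#'
#' @param x A [trace_matrix()].
#' @return A [trace_matrix()] over frames `[0, lh_start)`.
#' @export
truncate_basal <- function(x) {
  stopifnot(inherits(x, "trace_matrix"))
  g <- x$grid
  if (g$lh_start >= g$n_frames || g$lh_start == g$lh_end) {
    abort("No ligand window to remove: traces are already basal-only.")
  }
  if (g$lh_start < 1L) abort("Grid has no basal window.")
  new_grid <- time_grid(n_frames = g$lh_start, rate = g$rate,
                        lh_start = g$lh_start, lh_end = g$lh_start)
  trace_matrix(x$values[, seq_len(g$lh_start), drop = FALSE], x$meta, new_grid)
}

#' Save / load traces as plain-text CSV
#'
#' Writes `traces.csv` (cell_id + one `f0000...` column per frame),
#' `metadata.csv` (cell_id, group, animal_id, sex) and `grid.json` into a
#' directory; [load_traces()] restores the identical object.
#'
#' @param x A [trace_matrix()].
#' @param path Directory to write into (created if needed).
#' @return `save_traces()` returns `path` invisibly; `load_traces()` returns
#'   a [trace_matrix()].
#' @export
save_traces <- function(x, path) {
  stopifnot(inherits(x, "trace_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(x$values)
  df <- cbind(data.frame(cell_id = x$meta$cell_id), df)
  readr::write_csv(tibble::as_tibble(df), file.path(path, "traces.csv"))
  readr::write_csv(x$meta, file.path(path, "metadata.csv"))
  jsonlite::write_json(unclass(x$grid), file.path(path, "grid.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_traces
#' @export
load_traces <- function(path) {
  tr_file <- file.path(path, "traces.csv")
  meta_file <- file.path(path, "metadata.csv")
  grid_file <- file.path(path, "grid.json")
  for (f in c(tr_file, meta_file, grid_file)) {
    if (!file.exists(f)) abort(sprintf("Missing file: %s", f))
  }
  g <- jsonlite::read_json(grid_file, simplifyVector = TRUE)
  grid <- time_grid(g$n_frames, g$rate, g$lh_start, g$lh_end)
  traces <- readr::read_csv(tr_file, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_csv(meta_file, show_col_types = FALSE, progress = FALSE)
  if (!"cell_id" %in% names(traces)) abort("traces.csv lacks a `cell_id` column.")
  need <- c("cell_id", "group", "animal_id", "sex")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(sprintf("metadata.csv is missing column(s): %s.", paste(miss, collapse = ", ")))
  if (nrow(traces) != nrow(meta)) {
    abort(sprintf("traces.csv has %d rows but metadata.csv has %d.", nrow(traces), nrow(meta)))
  }
  if (!identical(as.character(traces$cell_id), as.character(meta$cell_id))) {
    abort("cell_id columns of traces.csv and metadata.csv do not match row-for-row.")
  }
  frame_cols <- grep("^f\\d+$", names(traces), value = TRUE)
  if (length(frame_cols) != grid$n_frames) {
    abort(sprintf("traces.csv has %d frame columns but grid.json declares %d frames.",
                  length(frame_cols), grid$n_frames))
  }
  values <- as.matrix(traces[, frame_cols])
  if (anyNA(values)) {
    bad <- which(rowSums(is.na(values)) > 0)[1]
    abort(sprintf("Missing trace values in row %d (cell_id %s).", bad, traces$cell_id[bad]))
  }
  trace_matrix(values, meta, grid)
}
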