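#' Normalize raw fluorescence to dF/F0
#'
#' Per cell, `dF/F0(t) = (F(t) - F0) / F0` with `F0` the mean of the cell's
#' raw values over the basal window. The result is scale invariant:
#' multiplying a cell's raw trace by any positive constant leaves its
#' normalized trace unchanged.
#'
#' @param raw Numeric cells x frames matrix of raw fluorescence, or a
#'   [trace_matrix()] holding raw values.
#' @param grid A [time_grid()] (ignored when `raw` is a trace_matrix).
#' @param meta Optional metadata data frame (see [trace_matrix()]); default
#'   metadata is synthesised when absent.
#'
#' @return A [trace_matrix()] of dF/F0 values.
#' @export
normalize_df_f0 <- function(raw, grid = NULL, meta = NULL) {
  if (inherits(raw, "trace_matrix")) {
    grid <- raw$grid
    meta <- raw$meta
    raw <- raw$values
  }
  if (is.null(grid)) abort("`grid` is required when `raw` is a bare matrix.")
  raw <- as_trace_values(raw)
  w <- resolve_window(grid, "BASAL")
  f0 <- rowMeans(raw[, window_cols(w), drop = FALSE])
  bad <- which(f0 <= 0)
  if (length(bad)) {
    ids <- if (!is.null(meta)) meta$cell_id[bad] else if (!is.null(rownames(raw))) rownames(raw)[bad] else bad
    abort(sprintf("Degenerate baseline (F0 <= 0) for cell(s): %s.",
                  paste(head(ids, 5), collapse = ", ")))
  }
  values <- sweep(sweep(raw, 1, f0, "-"), 1, f0, "/")
  if (is.null(meta)) {
    meta <- tibble(cell_id = sprintf("cell%04d", seq_len(nrow(raw))),
                   group = "unlabelled", animal_id = "unknown", sex = "unknown")
  }
  trace_matrix(values, meta, grid)
}

#' Windowed total-change statistic
#'
#' The per-frame mean dF/F0 within a window. Using the per-frame mean rather
#' than the raw sum keeps the 600-frame basal window and the 360-frame
#' ligand window directly comparable; the raw sum is also reported.
#'
#' @param traces A [trace_matrix()].
#' @param window A window name (`"BASAL"`, `"LH"`, `"WASH"`) or half-open
#'   0-based `c(start, end)`; may be a character vector of several names.
#' @return Tibble with columns `cell_id`, `group`, `window`, `total_change`
#'   (per-frame mean), `total_sum`.
#' @export
window_total_change <- function(traces, window = c("BASAL", "LH")) {
  stopifnot(inherits(traces, "trace_matrix"))
  windows <- if (is.character(window)) as.list(window) else list(window)
  map_dfr(windows, function(win) {
    w <- resolve_window(traces$grid, win)
    block <- traces$values[, window_cols(w), drop = FALSE]
    tibble(
      cell_id = traces$meta$cell_id,
      group = traces$meta$group,
      window = window_label(win),
      total_change = unname(rowMeans(block)),
      total_sum = unname(rowSums(block))
    )
  })
}

#' Windowed area under the curve
#'
#' Trapezoidal integral of dF/F0 against time in seconds. By default the
#' half-open window `[start, end)` is integrated over frames
#' `start ... end-1`; with `shared_endpoint = TRUE` integration extends to
#' the window-closing frame (capped at the last frame), a convention under
#' which BASAL + LH + WASH partitions the whole-trace AUC exactly.
#'
#' @inheritParams window_total_change
#' @param shared_endpoint Include the first frame of the following window as
#'   the closing trapezoid node (default `FALSE`).
#' @return Tibble with columns `cell_id`, `group`, `window`, `auc`
#'   (dF/F0 x seconds).
#' @export
window_auc <- function(traces, window = c("BASAL", "LH"), shared_endpoint = FALSE) {
  stopifnot(inherits(traces, "trace_matrix"))
  grid <- traces$grid
  windows <- if (is.character(window)) as.list(window) else list(window)
  map_dfr(windows, function(win) {
    w <- resolve_window(grid, win)
    last <- if (shared_endpoint) min(w[2] + 1L, grid$n_frames) else w[2]
    cols <- seq.int(w[1] + 1L, last)
    times <- (cols - 1L) / grid$rate
    block <- traces$values[, cols, drop = FALSE]
    auc <- if (length(cols) < 2L) rep(0, nrow(block)) else {
      unname(apply(block, 1L, function(y) pracma::trapz(times, y)))
    }
    tibble(
      cell_id = traces$meta$cell_id,
      group = traces$meta$group,
      window = window_label(win),
      auc = auc
    )
  })
}

#' Combined tidy window statistics
#'
#' @inheritParams window_total_change
#' @return Tibble `cell_id`, `group`, `window`, `total_change`, `auc`.
#' @export
window_stats <- function(traces, window = c("BASAL", "LH", "WASH")) {
  dplyr::left_join(
    window_total_change(traces, window),
    window_auc(traces, window),
    by = c("cell_id", "group", "window")
  ) |>
    select(-"total_sum")
}

#' Group mean traces with variability
#'
#' Frame-wise mean and standard deviation of dF/F0 across the cells of each
#' group, the basis of mean +/- SD trace figures. The per-group peak (the
#' maximum of the mean trace) and its frame are available via
#' [trace_peaks()].
#'
#' @param traces A [trace_matrix()].
#' @return Tibble with columns `group`, `frame` (0-based), `time_s`, `mean`,
#'   `sd`.
#' @export
group_mean_traces <- function(traces) {
  stopifnot(inherits(traces, "trace_matrix"))
  groups <- sort(unique(traces$meta$group))
  nf <- ncol(traces$values)
  map_dfr(groups, function(g) {
    rows <- traces$meta$group == g
    if (!any(rows)) abort(sprintf("Empty group '%s'.", g))
    block <- traces$values[rows, , drop = FALSE]
    tibble(
      group = g,
      frame = seq_len(nf) - 1L,
      time_s = (seq_len(nf) - 1L) / traces$grid$rate,
      mean = unname(colMeans(block)),
      sd = if (nrow(block) == 1L) rep(0, nf) else unname(apply(block, 2L, sd))
    )
  })
}

#' Peak of each group mean trace
#'
#' @param group_traces Output of [group_mean_traces()].
#' @return Tibble `group`, `peak` (max of the mean trace), `peak_frame`
#'   (0-based argmax).
#' @export
trace_peaks <- function(group_traces) {
  group_traces |>
    group_by(.data$group) |>
    summarise(peak = max(.data$mean),
              peak_frame = .data$frame[which.max(.data$mean)],
              .groups = "drop")
}

#' Heatmap row order
#'
#' Cells sorted by their ligand-window total-change statistic in descending
#' order (ties broken by `cell_id`, ascending), the order used to display
#' response heatmaps.
#'
#' @param traces A [trace_matrix()].
#' @return Integer permutation of `1:n_cells`.
#' @export
heatmap_order <- function(traces) {
  stats <- window_total_change(traces, "LH")
  order(-stats$total_change, stats$cell_id)
}

#' Per-group inactive-cell fractions
#'
#' A cell is inactive in a window when its maximum dF/F0 there stays below
#' `threshold` (default 0.1): any supra-threshold transient marks a cell as
#' active.
#'
#' @inheritParams window_total_change
#' @param threshold Activity threshold in dF/F0 units (default 0.1).
#' @return Tibble `group`, `window`, `n_cells`, `n_inactive`, `fraction`.
#' @export
inactive_fraction <- function(traces, window = "LH", threshold = 0.1) {
  stopifnot(inherits(traces, "trace_matrix"))
  w <- resolve_window(traces$grid, window)
  peak <- unname(apply(traces$values[, window_cols(w), drop = FALSE], 1L, max))
  tibble(group = traces$meta$group, inactive = peak < threshold) |>
    group_by(.data$group) |>
    summarise(window = window_label(window),
              n_cells = dplyr::n(),
              n_inactive = sum(.data$inactive),
              fraction = mean(.data$inactive),
              .groups = "drop")
}

#' First-minute ligand window
#'
#' Convenience for the window covering the first `minutes` of ligand
#' application.
#'
#' @param grid A [time_grid()].
#' @param minutes Number of minutes from ligand onset (default 1).
#' @return Half-open 0-based `c(start, end)` frame range.
#' @export
first_lh_window <- function(grid, minutes = 1) {
  stopifnot(inherits(grid, "time_grid"))
  end <- min(grid$lh_start + as.integer(round(minutes * 60 * grid$rate)), grid$lh_end)
  c(grid$lh_start, end)
}
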