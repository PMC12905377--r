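#' Recording time grid
#'
#' Describes the temporal layout of a calcium-imaging recording: the number
#' of frames, the acquisition rate, and the half-open frame window during
#' which the ligand (e.g. luteinizing hormone) is bath-applied. Frames are
#' indexed from 0, so the default grid corresponds to a 12.5-minute
#' recording at 2 Hz with a basal period over frames 0-599, ligand
#' application over frames 600-959 (3 min), and washout afterwards.
#'
#' @param n_frames Number of frames in the recording (default 1500).
#' @param rate Acquisition rate in frames per second (default 2).
#' @param lh_start First frame (0-based) of ligand application (default 600).
#' @param lh_end One-past-last frame of ligand application (default 960).
#'
#' @return A `time_grid` object.
#' @examples
#' grid <- time_grid()
#' grid_windows(grid)
#' @export
time_grid <- function(n_frames = 1500L, rate = 2, lh_start = 600L, lh_end = 960L) {
  check_scalar_number(n_frames, "n_frames", min = 1)
  check_scalar_number(rate, "rate")
  check_scalar_number(lh_start, "lh_start", min = 0)
  check_scalar_number(lh_end, "lh_end", min = 0)
  if (rate <= 0) abort("`rate` must be positive.")
  if (!(lh_start <= lh_end && lh_end <= n_frames)) {
    abort("Require 0 <= lh_start <= lh_end <= n_frames.")
  }
  structure(
    list(
      n_frames = as.integer(n_frames),
      rate = rate,
      lh_start = as.integer(lh_start),
      lh_end = as.integer(lh_end)
    ),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> %d frames @ %g Hz (%.1f min); ligand window frames [%d, %d)\n",
    x$n_frames, x$rate, x$n_frames / x$rate / 60, x$lh_start, x$lh_end
  ))
  invisible(x)
}

#' Named analysis windows of a time grid
#'
#' @param grid A [time_grid()].
#' @return A named list of half-open 0-based frame ranges `c(start, end)` for
#'   the `BASAL`, `LH` and `WASH` windows.
#' @export
grid_windows <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  list(
    BASAL = c(0L, grid$lh_start),
    LH = c(grid$lh_start, grid$lh_end),
    WASH = c(grid$lh_end, grid$n_frames)
  )
}

#' Frame midpoint times in seconds
#'
#' @param grid A [time_grid()].
#' @return Numeric vector of length `n_frames`; frame `t` (0-based) occurs at
#'   `t / rate` seconds.
#' @export
frame_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  (seq_len(grid$n_frames) - 1) / grid$rate
}

# Resolve a window given as a name ("BASAL"/"LH"/"WASH") or an explicit
# half-open 0-based c(start, end). Empty windows are rejected here, which is
# where every windowed operation funnels through.
resolve_window <- function(grid, window) {
  stopifnot(inherits(grid, "time_grid"))
  if (is.character(window) && length(window) == 1L) {
    wins <- grid_windows(grid)
    if (!window %in% names(wins)) {
      abort(sprintf("Unknown window '%s'; expected BASAL, LH or WASH.", window))
    }
    w <- wins[[window]]
  } else if (is.numeric(window) && length(window) == 2L) {
    w <- as.integer(window)
  } else {
    abort("`window` must be 'BASAL', 'LH', 'WASH' or c(start, end).")
  }
  if (w[1] < 0 || w[2] > grid$n_frames || w[1] > w[2]) {
    abort(sprintf("Window [%d, %d) does not fit in a %d-frame grid.", w[1], w[2], grid$n_frames))
  }
  if (w[2] - w[1] < 1L) abort("Empty window.")
  w
}

window_label <- function(window) {
  if (is.character(window)) window else sprintf("[%d,%d)", window[1], window[2])
}

# 1-based column indices of a resolved half-open window
window_cols <- function(w) seq.int(w[1] + 1L, w[2])
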