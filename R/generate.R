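#' Generate a labelled synthetic calcium-trace cohort
#'
#' Simulates one dF/F0 trace per cell under the generative model described
#' in [group_params()]: basal sinusoid + random-walk drift + white noise for
#' every cell, plus a ligand response (delayed saturating rise, plateau,
#' exponential washout) for the per-cell Bernoulli responders. Bit-identical
#' output for identical `(config, seed)`; animal ids are assigned round-robin
#' within each group.
#'
#' @param config A [cohort_config()], e.g. from [default_cohort_config()].
#' @param seed Optional override of `config$seed`.
#'
#' @return A [trace_matrix()].
#' @examples
#' tm <- generate_cohort(default_cohort_config("male"))
#' tm
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- as.integer(seed %||% config$seed)
  grid <- config$grid
  tt <- frame_times(grid)
  t_on <- grid$lh_start / grid$rate
  t_off <- grid$lh_end / grid$rate

  total <- sum(vapply(config$groups, function(s) s$n_cells, integer(1)))
  values <- matrix(0, nrow = total, ncol = grid$n_frames)
  cell_id <- character(total)
  group <- character(total)
  animal_id <- character(total)

  withr::with_seed(seed, {
    row <- 0L
    for (g in names(config$groups)) {
      spec <- config$groups[[g]]
      p <- spec$params
      for (j in seq_len(spec$n_cells)) {
        row <- row + 1L
        trace <- simulate_basal(p, tt)
        if (runif(1) < p$responder_fraction) {
          trace <- trace + simulate_response(p, tt, t_on, t_off)
        } else {
          # keep the RNG stream aligned so responder status of one cell does
          # not shift every later cell's draws
          rnorm(2)
        }
        values[row, ] <- trace
        cell_id[row] <- sprintf("%s_%s_c%04d", substr(config$sex, 1, 1), g, j)
        animal_id[row] <- sprintf("%s_%s_a%d", substr(config$sex, 1, 1), g,
                                  ((j - 1L) %% spec$n_animals) + 1L)
        group[row] <- g
      }
    }
  })

  meta <- tibble(cell_id = cell_id, group = group,
                 animal_id = animal_id, sex = config$sex)
  trace_matrix(values, meta, grid)
}

# Basal component: sinusoid with per-cell random frequency/phase + Gaussian
# random-walk drift scaled to terminal SD drift_amp + iid noise.
simulate_basal <- function(p, tt) {
  nf <- length(tt)
  freq <- runif(1, p$basal_osc_freq_range[1], p$basal_osc_freq_range[2])
  phase <- runif(1, 0, 2 * pi)
  osc <- p$basal_osc_amp * sin(2 * pi * freq * tt + phase)
  drift <- p$drift_amp * cumsum(rnorm(nf)) / sqrt(nf)
  noise <- rnorm(nf, 0, p$noise_sd)
  osc + drift + noise
}

# Ligand response: zero before onset + latency; saturating rise with
# time-constant rise_tau until the end of application; exponential decay
# with decay_tau afterwards. Latencies that overrun the application window
# yield a silent (inactive) responder.
simulate_response <- function(p, tt, t_on, t_off) {
  amp <- max(rnorm(1, p$peak_amp_mean, p$peak_amp_sd), 0)
  lat <- max(rnorm(1, p$latency_mean, p$latency_sd), 0)
  t0 <- t_on + lat
  resp <- numeric(length(tt))
  if (t0 >= t_off || amp == 0) return(resp)
  rise_tau <- max(p$rise_tau, 1e-9)
  decay_tau <- max(p$decay_tau, 1e-9)
  rise <- tt >= t0 & tt < t_off
  resp[rise] <- amp * (1 - exp(-(tt[rise] - t0) / rise_tau))
  v_end <- amp * (1 - exp(-(t_off - t0) / rise_tau))
  wash <- tt >= t_off
  resp[wash] <- v_end * exp(-(tt[wash] - t_off) / decay_tau)
  resp
}
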