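#' Generative parameters for one experimental group
#'
#' Each synthetic cell is the sum of a basal component (one slow sinusoid
#' with per-cell random frequency and phase, a Gaussian random-walk drift,
#' and white noise) and, for responder cells only, a ligand-response
#' component: a saturating rise starting `latency` seconds after ligand
#' onset, a plateau through the end of the application window, and an
#' exponential washout decay.
#'
#' @param responder_fraction Probability that a cell responds to the ligand.
#' @param peak_amp_mean,peak_amp_sd Mean and SD of the per-cell response
#'   amplitude (dF/F0 units); draws are truncated at 0.
#' @param latency_mean,latency_sd Mean and SD of the per-cell response
#'   latency in seconds after ligand onset; draws are truncated at 0.
#' @param rise_tau,decay_tau Rise and washout-decay time constants (seconds).
#' @param basal_osc_amp Amplitude of the basal sinusoid (dF/F0 units).
#' @param basal_osc_freq_range Length-2 range (Hz) from which each cell's
#'   basal oscillation frequency is drawn uniformly.
#' @param drift_amp Terminal standard deviation of the random-walk drift
#'   (dF/F0 units).
#' @param noise_sd SD of the white measurement noise (dF/F0 units).
#'
#' @return A `group_params` object (named list).
#' @export
group_params <- function(responder_fraction = 0,
                         peak_amp_mean = 0, peak_amp_sd = 0,
                         latency_mean = 0, latency_sd = 0,
                         rise_tau = 10, decay_tau = 40,
                         basal_osc_amp = 0,
                         basal_osc_freq_range = c(0.01, 0.05),
                         drift_amp = 0, noise_sd = 0) {
  check_scalar_number(responder_fraction, "responder_fraction", 0, 1)
  for (nm in c("peak_amp_mean", "peak_amp_sd", "latency_mean", "latency_sd",
               "rise_tau", "decay_tau", "basal_osc_amp", "drift_amp", "noise_sd")) {
    check_scalar_number(get(nm), nm, min = 0)
  }
  if (!is.numeric(basal_osc_freq_range) || length(basal_osc_freq_range) != 2L ||
      any(!is.finite(basal_osc_freq_range)) || any(basal_osc_freq_range < 0) ||
      basal_osc_freq_range[1] > basal_osc_freq_range[2]) {
    abort("`basal_osc_freq_range` must be a non-decreasing, non-negative length-2 range (Hz).")
  }
  structure(
    list(
      responder_fraction = responder_fraction,
      peak_amp_mean = peak_amp_mean, peak_amp_sd = peak_amp_sd,
      latency_mean = latency_mean, latency_sd = latency_sd,
      rise_tau = rise_tau, decay_tau = decay_tau,
      basal_osc_amp = basal_osc_amp,
      basal_osc_freq_range = basal_osc_freq_range,
      drift_amp = drift_amp, noise_sd = noise_sd
    ),
    class = "group_params"
  )
}

#' Assemble a cohort configuration
#'
#' @param groups Named list; names are group labels (`HET`, `HOM`,
#'   `HOM_TREATED`) and each element is a list with entries `params`
#'   ([group_params()]), `n_cells`, `n_animals`, and optionally
#'   `peak_target` (the calibration target for the group mean-trace peak).
#' @param grid A [time_grid()].
#' @param sex Cohort tag, `"male"` or `"female"`.
#' @param seed Integer seed making [generate_cohort()] deterministic.
#'
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(groups, grid = time_grid(), sex = "female", seed = 1L) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named list of group specifications.")
  }
  allowed <- c("HET", "HOM", "HOM_TREATED")
  if (!all(names(groups) %in% allowed)) {
    abort(sprintf("Group labels must be among: %s.", paste(allowed, collapse = ", ")))
  }
  for (g in names(groups)) {
    spec <- groups[[g]]
    if (!inherits(spec$params, "group_params")) {
      abort(sprintf("groups$%s$params must be a group_params object.", g))
    }
    check_scalar_number(spec$n_cells %||% 0, sprintf("groups$%s$n_cells", g), min = 1)
    check_scalar_number(spec$n_animals %||% 1, sprintf("groups$%s$n_animals", g), min = 1)
    groups[[g]]$n_cells <- as.integer(spec$n_cells)
    groups[[g]]$n_animals <- as.integer(spec$n_animals %||% 1)
  }
  sex <- match.arg(sex, c("male", "female"))
  check_scalar_number(seed, "seed")
  structure(
    list(groups = groups, grid = grid, sex = sex, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> sex=%s seed=%d\n", x$sex, x$seed))
  for (g in names(x$groups)) {
    s <- x$groups[[g]]
    cat(sprintf(
      "  %-12s n_cells=%4d n_animals=%d responder=%.2f amp=%.3f peak_target=%s\n",
      g, s$n_cells, s$n_animals, s$params$responder_fraction,
      s$params$peak_amp_mean, format(s$peak_target %||% NA)
    ))
  }
  print(x$grid)
  invisible(x)
}

#' Default study-calibrated cohort configurations
#'
#' Returns the per-sex default synthetic cohorts. Group mean-trace peak
#' targets are 0.40 (HET) and 0.23 (HOM) for the male cohort and 0.28 (HET),
#' 0.055 (HOM) and 0.32 (HOM_TREATED) for the female cohort; cell counts are
#' 278/175 (male) and 401/203/391 (female). Treated cells are control-like
#' but with delayed response kinetics, so that roughly 37% are still
#' inactive (< 0.1 dF/F0) during the first minute of ligand application,
#' against roughly 16.5% of control cells. Control and mutant groups also
#' differ in their basal oscillation band, which is what makes basal-only
#' classification possible.
#'
#' @param sex `"male"` or `"female"`.
#' @param seed Seed stored in the config (default 1).
#' @return A [cohort_config()].
#' @examples
#' cfg <- default_cohort_config("male")
#' cfg$groups$HET$peak_target
#' @export
default_cohort_config <- function(sex = c("male", "female"), seed = 1L) {
  sex <- match.arg(sex)
  het_basal <- list(basal_osc_amp = 0.035, basal_osc_freq_range = c(0.01, 0.08),
                    drift_amp = 0.02, noise_sd = 0.018)
  hom_basal <- list(basal_osc_amp = 0.024, basal_osc_freq_range = c(0.05, 0.14),
                    drift_amp = 0.013, noise_sd = 0.018)
  if (sex == "male") {
    groups <- list(
      HET = list(
        params = do.call(group_params, c(list(
          responder_fraction = 0.85, peak_amp_mean = 0.47, peak_amp_sd = 0.18,
          latency_mean = 8, latency_sd = 5, rise_tau = 12, decay_tau = 45
        ), het_basal)),
        n_cells = 278L, n_animals = 5L, peak_target = 0.40
      ),
      HOM = list(
        params = do.call(group_params, c(list(
          responder_fraction = 0.62, peak_amp_mean = 0.363, peak_amp_sd = 0.10,
          latency_mean = 16, latency_sd = 8, rise_tau = 28, decay_tau = 70
        ), hom_basal)),
        n_cells = 175L, n_animals = 5L, peak_target = 0.23
      )
    )
  } else {
    groups <- list(
      HET = list(
        params = do.call(group_params, c(list(
          responder_fraction = 0.85, peak_amp_mean = 0.33, peak_amp_sd = 0.15,
          latency_mean = 8, latency_sd = 5, rise_tau = 12, decay_tau = 45
        ), het_basal)),
        n_cells = 401L, n_animals = 5L, peak_target = 0.28
      ),
      HOM = list(
        params = do.call(group_params, c(list(
          responder_fraction = 0.25, peak_amp_mean = 0.195, peak_amp_sd = 0.08,
          latency_mean = 8, latency_sd = 5, rise_tau = 12, decay_tau = 45
        ), hom_basal)),
        n_cells = 203L, n_animals = 5L, peak_target = 0.055
      ),
      HOM_TREATED = list(
        params = do.call(group_params, c(list(
          responder_fraction = 0.88, peak_amp_mean = 0.35, peak_amp_sd = 0.16,
          latency_mean = 40, latency_sd = 24, rise_tau = 15, decay_tau = 45
        ), het_basal)),
        n_cells = 391L, n_animals = 3L, peak_target = 0.32
      )
    )
  }
  cohort_config(groups, grid = time_grid(), sex = sex, seed = seed)
}

#' Serialize / restore a cohort configuration
#'
#' Writes the full configuration — grid, seed, sex, and per-group
#' generative parameters — as YAML or JSON (chosen by file extension).
#' The schema mirrors the object: top-level `sex`, `seed`, `grid`
#' (n_frames, rate, lh_start, lh_end) and `groups`, a map from group label
#' to `n_cells`, `n_animals`, optional `peak_target`, and `params` holding
#' every [group_params()] field.
#'
#' @param config A [cohort_config()].
#' @param path Output file ending in `.yaml`/`.yml` or `.json`.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns a [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  obj <- list(
    sex = config$sex, seed = config$seed, grid = unclass(config$grid),
    groups = lapply(config$groups, function(g) {
      list(n_cells = g$n_cells, n_animals = g$n_animals,
           peak_target = g$peak_target, params = unclass(g$params))
    })
  )
  if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("The yaml package is required to write YAML configs.")
    }
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such config file: %s", path))
  obj <- if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("The yaml package is required to read YAML configs.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(obj$groups)) abort("Config lacks a `groups` entry.")
  groups <- lapply(obj$groups, function(g) {
    params <- g$params
    params$basal_osc_freq_range <- as.numeric(params$basal_osc_freq_range)
    list(params = do.call(group_params, params),
         n_cells = g$n_cells, n_animals = g$n_animals,
         peak_target = g$peak_target)
  })
  grid <- if (is.null(obj$grid)) time_grid() else
    time_grid(obj$grid$n_frames, obj$grid$rate, obj$grid$lh_start, obj$grid$lh_end)
  cohort_config(groups, grid = grid, sex = obj$sex %||% "female",
                seed = obj$seed %||% 1L)
}
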