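# Shared fixtures, all generated in code.

tiny_grid <- function(n_frames = 100L, rate = 2, lh_start = 40L, lh_end = 70L) {
  time_grid(n_frames, rate, lh_start, lh_end)
}

flat_params <- function(...) {
  do.call(group_params, utils::modifyList(list(
    responder_fraction = 0.9, peak_amp_mean = 0.4, peak_amp_sd = 0.1,
    latency_mean = 10, latency_sd = 5, rise_tau = 12, decay_tau = 45,
    basal_osc_amp = 0.03, basal_osc_freq_range = c(0.01, 0.06),
    drift_amp = 0.015, noise_sd = 0.018), list(...)))
}

# a small cohort on the full-size grid
small_cohort <- function(n = 30, seed = 7, grid = time_grid()) {
  cohort_config(list(
    HET = list(params = flat_params(), n_cells = n, n_animals = 3),
    HOM = list(params = flat_params(responder_fraction = 0.3, peak_amp_mean = 0.2),
               n_cells = n, n_animals = 3)
  ), grid = grid, seed = seed) |> generate_cohort()
}

# two groups drawn from identical parameters: no class signal by construction
null_cohort <- function(n = 60, seed = 5, grid = time_grid()) {
  p <- flat_params()
  cohort_config(list(
    HET = list(params = p, n_cells = n, n_animals = 3),
    HOM = list(params = p, n_cells = n, n_animals = 3)
  ), grid = grid, seed = seed) |> generate_cohort()
}

# two well-separated Gaussian blobs in `d` dimensions, centers `sep` apart
blob_matrix <- function(n_per = 50, d = 10, sep = 10, sigma = 0.1, seed = 1) {
  withr::with_seed(seed, {
    rbind(matrix(rnorm(n_per * d, 0, sigma), ncol = d),
          matrix(rnorm(n_per * d, sep / sqrt(d), sigma), ncol = d))
  })
}

blob_labels <- function(n_per = 50) rep(c("A", "B"), each = n_per)

# agreement between binary cluster assignments and true blob labels,
# maximized over the label swap
blob_agreement <- function(cluster, n_per = 50) {
  truth <- rep(1:2, each = n_per)
  max(mean(cluster == truth), mean(cluster == (3L - truth)))
}

# binomial 95% interval (in accuracy %) around chance level p0
chance_interval <- function(p0, n) {
  half <- 1.96 * sqrt(p0 * (1 - p0) / n)
  100 * c(p0 - half, p0 + half)
}
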