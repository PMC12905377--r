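test_that("generation is deterministic and bookkeeping is exact", {
  cfg <- default_cohort_config("male", seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$values, b$values)
  expect_identical(a$meta, b$meta)
  expect_false(identical(a$values, generate_cohort(cfg, seed = 4)$values))

  expect_equal(nrow(a$meta), 278 + 175)
  expect_false(anyNA(a$values))
  expect_equal(sum(a$meta$group == "HET"), 278)
  expect_equal(sum(a$meta$group == "HOM"), 175)
  # every cell has exactly one group and one animal id, round-robin over 5
  expect_true(all(table(a$meta$animal_id[a$meta$group == "HET"]) %in% 55:56))
})

test_that("all signal sources at zero give identically zero traces", {
  cfg <- cohort_config(list(
    HET = list(params = group_params(responder_fraction = 1), n_cells = 4, n_animals = 2)
  ), grid = tiny_grid(), seed = 1)
  tm <- generate_cohort(cfg)
  expect_true(all(tm$values == 0))
})

test_that("responder model matches its closed form for a noiseless cell", {
  grid <- time_grid(200, rate = 2, lh_start = 80, lh_end = 140)
  p <- group_params(responder_fraction = 1, peak_amp_mean = 0.5, peak_amp_sd = 0,
                    latency_mean = 4, latency_sd = 0, rise_tau = 10, decay_tau = 20)
  tm <- generate_cohort(cohort_config(
    list(HET = list(params = p, n_cells = 1, n_animals = 1)), grid = grid, seed = 2))
  tt <- frame_times(grid)
  t0 <- 40 + 4; t_end <- 70
  expected <- numeric(200)
  ris <- tt >= t0 & tt < t_end
  expected[ris] <- 0.5 * (1 - exp(-(tt[ris] - t0) / 10))
  v_end <- 0.5 * (1 - exp(-(t_end - t0) / 10))
  expected[tt >= t_end] <- v_end * exp(-(tt[tt >= t_end] - t_end) / 20)
  expect_equal(unname(tm$values[1, ]), expected, tolerance = 1e-12)
})

test_that("default cohorts hit their configured mean-trace peak targets", {
  # average-of-realizations check across seeds, +/-15% of configured target
  for (sex in c("male", "female")) {
    cfg <- default_cohort_config(sex)
    targets <- vapply(cfg$groups, function(g) g$peak_target, numeric(1))
    peaks <- purrr::map_dfr(1:3, function(s)
      trace_peaks(group_mean_traces(generate_cohort(cfg, seed = s))))
    mean_peaks <- tapply(peaks$peak, peaks$group, mean)
    expect_true(all(abs(mean_peaks[names(targets)] - targets) / targets < 0.15),
                info = sex)
  }
})

test_that("control exceeds mutant mean ligand-window signal in the male defaults", {
  tm <- generate_cohort(default_cohort_config("male", seed = 9))
  lh <- window_total_change(tm, "LH")
  m <- tapply(lh$total_change, lh$group, mean)
  expect_gt(m[["HET"]], m[["HOM"]])
})

test_that("invalid generator inputs are rejected", {
  expect_error(group_params(responder_fraction = 1.2), "responder_fraction")
  expect_error(group_params(noise_sd = -1), "noise_sd")
  expect_error(group_params(peak_amp_mean = NaN), "finite")
  expect_error(group_params(basal_osc_freq_range = c(0.5, 0.1)), "freq_range")
  expect_error(default_cohort_config("other"), "arg")
  expect_error(cohort_config(list(BAD = list(params = group_params(), n_cells = 2))),
               "labels")
})

test_that("cohort configs round-trip through JSON and YAML", {
  cfg <- default_cohort_config("female", seed = 9)
  for (ext in c("json", "yaml")) {
    if (ext == "yaml") skip_if_not_installed("yaml")
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_cohort_config(cfg, path)
    back <- read_cohort_config(path)
    expect_equal(back$sex, cfg$sex)
    expect_equal(back$seed, cfg$seed)
    expect_equal(unclass(back$grid), unclass(cfg$grid))
    for (g in names(cfg$groups)) {
      expect_equal(unclass(back$groups[[g]]$params),
                   unclass(cfg$groups[[g]]$params), tolerance = 1e-12)
      expect_equal(back$groups[[g]]$n_cells, cfg$groups[[g]]$n_cells)
    }
    # identical configs generate identical cohorts
    expect_identical(generate_cohort(back)$values, generate_cohort(cfg)$values)
  }
})
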