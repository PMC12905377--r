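test_that("dF/F0 normalization matches the per-element formula and is scale invariant", {
  grid <- tiny_grid()
  set.seed(1)
  raw <- matrix(runif(6 * 100, min = 50, max = 150), nrow = 6)
  tm <- normalize_df_f0(raw, grid)
  f0 <- rowMeans(raw[, 1:40])
  expect_equal(unname(tm$values), (raw - f0) / f0, tolerance = 1e-12)

  # constant raw trace -> all zeros; single excursion -> exact arithmetic
  const <- matrix(100, 2, 100)
  const[2, 50] <- 150
  tm2 <- normalize_df_f0(const, grid)
  expect_true(all(tm2$values[1, ] == 0))
  f0_2 <- mean(const[2, 1:40])
  expect_equal(unname(tm2$values[2, 50]), (150 - f0_2) / f0_2)

  # scale invariance: normalize(c * raw) == normalize(raw) for c > 0
  expect_equal(normalize_df_f0(3.7 * raw, grid)$values, tm$values, tolerance = 1e-12)

  bad <- raw; bad[3, 1:40] <- -bad[3, 1:40]
  expect_error(normalize_df_f0(bad, grid), "cell")
})

test_that("windowed total change distinguishes basal and ligand windows", {
  grid <- tiny_grid()
  v <- matrix(0, 2, 100)
  v[1, 41:70] <- 1  # exactly the LH window
  meta <- tibble::tibble(cell_id = c("a", "b"), group = "HET",
                         animal_id = "x", sex = "male")
  tm <- trace_matrix(v, meta, grid)
  ws <- window_total_change(tm, c("BASAL", "LH"))
  expect_equal(ws$total_change[ws$cell_id == "a" & ws$window == "LH"], 1)
  expect_equal(ws$total_change[ws$cell_id == "a" & ws$window == "BASAL"], 0)
  expect_true(all(ws$total_change[ws$cell_id == "b"] == 0))
  expect_error(window_total_change(tm, c(10, 10)), "Empty")
})

test_that("responders gain signal during ligand application", {
  tm <- small_cohort(n = 40)
  ws <- window_total_change(tm, c("BASAL", "LH")) |>
    tidyr::pivot_wider(id_cols = c("cell_id", "group"), names_from = "window",
                       values_from = "total_change")
  het <- ws[ws$group == "HET", ]
  expect_gt(mean(het$LH > het$BASAL), 0.9)
})

test_that("window AUC matches closed-form trapezoids and partitions the trace", {
  grid <- tiny_grid()  # rate 2
  meta <- tibble::tibble(cell_id = "a", group = "g", animal_id = "x", sex = "m")
  # constant v over the 30-frame LH window: AUC = v*(L-1)/rate
  v <- matrix(0, 1, 100); v[1, 41:70] <- 0.8
  tm <- trace_matrix(v, meta, grid)
  expect_equal(window_auc(tm, "LH")$auc, 0.8 * 29 / 2)
  expect_equal(window_auc(tm, "BASAL")$auc, 0)

  # triangle pulse of height h across k frames: AUC = h*(k-1)/(2*rate)
  h <- 0.6; k <- 21
  tri <- matrix(0, 1, 100)
  tri[1, 41:61] <- h * (1 - abs(seq(-1, 1, length.out = k)))
  tm_tri <- trace_matrix(tri, meta, grid)
  expect_equal(window_auc(tm_tri, c(40, 61))$auc, 0.5 * h * (k - 1) / 2,
               tolerance = 1e-12)

  # BASAL + LH + WASH partitions the whole trace under the shared-endpoint rule
  set.seed(2)
  rnd <- matrix(rnorm(3 * 100), 3, 100)
  meta3 <- tibble::tibble(cell_id = letters[1:3], group = "g",
                          animal_id = "x", sex = "m")
  tm_r <- trace_matrix(rnd, meta3, grid)
  parts <- window_auc(tm_r, c("BASAL", "LH", "WASH"), shared_endpoint = TRUE)
  whole <- window_auc(tm_r, c(0, 100))
  sums <- tapply(parts$auc, parts$cell_id, sum)
  expect_equal(as.numeric(sums[whole$cell_id]), whole$auc, tolerance = 1e-10)
})

test_that("group mean traces report exact peaks and degenerate SD", {
  grid <- tiny_grid()
  v <- rbind(seq_len(100) / 100, rep(0.5, 100))
  meta <- tibble::tibble(cell_id = c("a", "b"), group = c("HET", "HOM"),
                         animal_id = "x", sex = "m")
  tm <- trace_matrix(v, meta, grid)
  gt <- group_mean_traces(tm)
  expect_true(all(gt$sd == 0))  # single cell per group
  pk <- trace_peaks(gt)
  expect_equal(pk$peak[pk$group == "HET"], 1)
  expect_equal(pk$peak_frame[pk$group == "HET"], 99)
  # peak equals max of the mean trace by definition
  expect_equal(pk$peak, tapply(gt$mean, gt$group, max)[pk$group], ignore_attr = TRUE)
})

test_that("heatmap order sorts by ligand response and is a permutation", {
  grid <- tiny_grid()
  v <- matrix(0, 3, 100)
  v[1, 41:70] <- 0.1; v[2, 41:70] <- 0.9; v[3, 41:70] <- 0.5
  meta <- tibble::tibble(cell_id = c("c1", "c2", "c3"), group = "g",
                         animal_id = "x", sex = "m")
  tm <- trace_matrix(v, meta, grid)
  expect_equal(heatmap_order(tm), c(2L, 3L, 1L))

  # all-equal statistics: tie rule gives identity order by cell_id
  tm_eq <- trace_matrix(matrix(0.2, 3, 100), meta, grid)
  expect_equal(heatmap_order(tm_eq), 1:3)

  ord <- heatmap_order(small_cohort(n = 25))
  expect_setequal(ord, seq_along(ord))
  stats <- window_total_change(small_cohort(n = 25), "LH")$total_change
  expect_true(all(diff(stats[ord]) <= 1e-12))
})

test_that("inactive fractions follow the window-maximum rule", {
  grid <- tiny_grid()
  meta <- tibble::tibble(cell_id = c("a", "b"), group = c("g1", "g2"),
                         animal_id = "x", sex = "m")
  tm0 <- trace_matrix(matrix(0, 2, 100), meta, grid)
  expect_true(all(inactive_fraction(tm0, "LH")$fraction == 1))
  tm5 <- trace_matrix(matrix(0.5, 2, 100), meta, grid)
  expect_true(all(inactive_fraction(tm5, "LH")$fraction == 0))
  # a single above-threshold transient makes a cell active
  v <- matrix(0, 2, 100); v[1, 55] <- 0.2
  tm1 <- trace_matrix(v, meta, grid)
  fr <- inactive_fraction(tm1, "LH")
  expect_equal(fr$fraction[fr$group == "g1"], 0)
  expect_equal(fr$fraction[fr$group == "g2"], 1)
})
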