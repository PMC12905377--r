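test_that("reported accuracy and macro-F1 match the confusion-matrix oracle", {
  set.seed(4)
  truth <- sample(c("HET", "HOM", "HOM_TREATED"), 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.6, truth,
                 sample(c("HET", "HOM", "HOM_TREATED"), 300, replace = TRUE))
  m <- calcitrace:::classification_metrics(truth, pred)
  o <- oracle_metrics(truth, pred)
  expect_equal(m$accuracy, o$accuracy, tolerance = 1e-12)
  expect_equal(m$f1_macro, o$f1_macro, tolerance = 1e-12)
})

test_that("the feature net trains, predicts normalized probabilities and is reproducible", {
  tm <- small_cohort(n = 50, grid = tiny_grid())
  sp <- stratified_split(tm, seed = 1)
  cfg <- feature_net_config(input_dim = 100, hidden1 = 64, hidden2 = 16,
                            max_epochs = 60, seed = 3)
  net <- train_feature_net(tm, sp, cfg)
  pr <- predict(net, tm, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, n_cells(tm)), tolerance = 1e-6)
  expect_true(all(predict(net, tm) %in% c("HET", "HOM")))
  # accuracy in the report equals the oracle recomputation
  truth <- tm$meta$group[sp$test]
  pred <- predict(net, tm$values[sp$test, ])
  expect_equal(net$report$accuracy, oracle_metrics(truth, pred)$accuracy)

  net2 <- train_feature_net(tm, sp, cfg)
  expect_identical(net$par, net2$par)

  g <- glance(net)
  expect_equal(g$accuracy, net$report$accuracy)
  td <- tidy(net)
  expect_setequal(td$class, c("HET", "HOM"))
  expect_true(all(td$precision >= 0 & td$precision <= 1))

  expect_error(train_feature_net(tm, sp, feature_net_config(input_dim = 999)),
               "input_dim")
})

test_that("hidden features are the deterministic z2 pre-activations", {
  tm <- small_cohort(n = 30, grid = tiny_grid())
  sp <- stratified_split(tm, seed = 2)
  net <- train_feature_net(tm, sp, feature_net_config(
    input_dim = 100, hidden1 = 32, hidden2 = 8, max_epochs = 30, seed = 1))
  z <- extract_features(net, tm)
  expect_equal(dim(z), c(60L, 8L))
  expect_identical(z, extract_features(net, tm))

  # zero-weight model: embedding collapses to the broadcast bias b2
  zero_net <- net
  for (l in 1:3) zero_net$par$W[[l]][] <- 0
  zero_net$par$b[[2]] <- seq_len(8) / 10
  z0 <- extract_features(zero_net, tm)
  expect_equal(unname(z0), matrix(seq_len(8) / 10, 60, 8, byrow = TRUE))
})

test_that("learned features separate classes at least as well as raw traces", {
  tm <- small_cohort(n = 60)
  sp <- stratified_split(tm, seed = 3)
  net <- train_feature_net(tm, sp, feature_net_config(max_epochs = 80, seed = 4))
  z <- extract_features(net, tm)
  pur_z <- mean(cluster_kmeans(z, 2, seed = 1, labels = tm$meta$group)$composition$purity)
  pur_raw <- mean(cluster_kmeans(tm, 2, seed = 1, silhouette = FALSE)$composition$purity)
  expect_gte(pur_z + 1e-9, pur_raw * 0.95)  # allow slack of one cell either way
})

test_that("transfer percentages reduce to recall on held-out control/mutant copies", {
  tm <- small_cohort(n = 60, grid = tiny_grid())
  sp <- stratified_split(tm, seed = 5)
  net <- train_feature_net(tm, sp, feature_net_config(
    input_dim = 100, hidden1 = 64, hidden2 = 16, max_epochs = 60, seed = 5))
  test_tm <- tm[sp$test, ]
  het_rows <- test_tm$meta$group == "HET"
  pred <- predict(net, test_tm)
  het_recall <- 100 * mean(pred[het_rows] == "HET")
  hom_recall <- 100 * mean(pred[!het_rows] == "HOM")
  expect_equal(transfer_fraction_control(net, test_tm[het_rows, ]), het_recall)
  expect_equal(transfer_fraction_control(net, test_tm[!het_rows, ]), 100 - hom_recall)

  three <- net; three$classes <- c("HET", "HOM", "X")
  expect_error(transfer_fraction_control(three, test_tm), "binary")
})

test_that("the baseline suite has the published composition and a perfect linear case", {
  # linearly separable blobs: linear SVM must reach 100%
  m <- blob_matrix(n_per = 30, d = 20, sep = 8, seed = 10)
  meta <- tibble::tibble(cell_id = sprintf("c%02d", 1:60),
                         group = rep(c("HET", "HOM"), each = 30),
                         animal_id = "a", sex = "m")
  grid <- time_grid(n_frames = 20, rate = 2, lh_start = 8, lh_end = 14)
  tm <- trace_matrix(m, meta, grid)
  sp <- stratified_split(tm, seed = 1)
  suite <- run_baseline_suite(tm, sp, include_feature_net = FALSE, seed = 1)
  expect_equal(nrow(suite), 8)
  expect_setequal(suite$model,
                  c("svm_rbf", "svm_linear", "logistic", "decision_tree", "knn",
                    "gaussian_nb", "random_forest", "mlp"))
  expect_equal(suite$accuracy[suite$model == "svm_linear"], 100)

  suite_fn <- run_baseline_suite(tm, sp, seed = 1,
                                 feature_net_config = feature_net_config(
                                   input_dim = 20, hidden1 = 32, hidden2 = 8,
                                   max_epochs = 40))
  expect_equal(nrow(suite_fn), 9)
  expect_true("feature_net" %in% suite_fn$model)
})

test_that("identical-parameter groups cannot be classified above chance", {
  accs <- purrr::map_dbl(1:2, function(s) {
    tm <- null_cohort(n = 50, seed = s, grid = tiny_grid(n_frames = 200,
                                                         lh_start = 80, lh_end = 140))
    sp <- stratified_split(tm, seed = s)
    net <- train_feature_net(tm, sp, feature_net_config(
      input_dim = 200, hidden1 = 64, hidden2 = 16, max_epochs = 80, seed = s))
    net$report$accuracy
  })
  band <- chance_interval(0.5, 2 * 20)  # pooled test cells over both seeds
  expect_gte(mean(accs), band[1])
  expect_lte(mean(accs), band[2])
})

test_that("training batches never touch test cells", {
  labels <- rep(c("HET", "HOM"), each = 40)
  sp <- stratified_split(labels, seed = 9)
  expect_length(intersect(sp$train, sp$test), 0)
  # the network only ever receives rows indexed by sp$train
  tm <- small_cohort(n = 40, grid = tiny_grid())
  net <- train_feature_net(tm, sp, feature_net_config(
    input_dim = 100, hidden1 = 16, hidden2 = 4, max_epochs = 5, seed = 1))
  expect_s3_class(net, "feature_net")
})
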