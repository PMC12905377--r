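#' Benchmark suite of classical classifiers
#'
#' Trains and evaluates the eight standard baselines with their published
#' hyperparameters — SVM with RBF kernel (C = 1, gamma = 1/(p * Var(X))),
#' linear SVM (C = 1), L2 logistic regression (C = 1), decision tree (gini,
#' no depth limit), k-nearest neighbours (k = 5, Euclidean), Gaussian naive
#' Bayes (variance smoothing 1e-9), random forest (50 trees, sqrt(p)
#' features) and a one-hidden-layer ReLU/Adam perceptron — plus, optionally,
#' the feature-learning network, reporting test-set accuracy and macro F1
#' for each.
#'
#' @param traces A [trace_matrix()].
#' @param split A [stratified_split()] over the same cells.
#' @param standardize Standardize features (per-frame z-score fitted on the
#'   training set) before the scale-sensitive models; default `FALSE`, as
#'   raw dF/F0 traces are used unless requested.
#' @param mlp_width Hidden-layer width of the perceptron baseline
#'   (default 400).
#' @param include_feature_net Append the feature-learning network row
#'   (default `TRUE`).
#' @param feature_net_config Configuration for that network; defaults to
#'   [feature_net_config()] with `input_dim` matched to the traces.
#' @param transfer_traces Optional [trace_matrix()] of cells from an unseen
#'   (treated) group; when supplied, each model also reports
#'   `treated_as_control_pct`, the percentage of those cells predicted HET.
#' @param seed Master seed; each model trains under its own derived seed.
#'
#' @return Tibble with one row per model: `model`, `hyperparameters`,
#'   `accuracy` (%), `f1_macro`, and `treated_as_control_pct` when
#'   `transfer_traces` is given. Per-class metrics are attached as the
#'   `per_class` attribute.
#' @export
run_baseline_suite <- function(traces, split, standardize = FALSE,
                               mlp_width = 400L, include_feature_net = TRUE,
                               feature_net_config = NULL, transfer_traces = NULL,
                               seed = 1L) {
  stopifnot(inherits(traces, "trace_matrix"), inherits(split, "split_spec"))
  X <- unname(traces$values)
  y <- traces$meta$group
  classes <- canonical_classes(y[split$train])
  if (length(classes) < 2L) abort("Training set must contain at least 2 classes.")
  ytr <- factor(y[split$train], levels = classes)
  yte <- y[split$test]
  Xtr <- X[split$train, , drop = FALSE]
  Xte <- X[split$test, , drop = FALSE]
  Xtreat <- if (!is.null(transfer_traces)) {
    tv <- as_trace_values(transfer_traces)
    if (ncol(tv) != ncol(X)) abort("`transfer_traces` frame count differs from `traces`.")
    unname(tv)
  }
  if (isTRUE(standardize)) {
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2L, sd)
    sg[sg < 1e-12] <- 1
    scale_fn <- function(M) sweep(sweep(M, 2, mu), 2, sg, "/")
    Xtr <- scale_fn(Xtr); Xte <- scale_fn(Xte)
    if (!is.null(Xtreat)) Xtreat <- scale_fn(Xtreat)
  }

  fits <- list(
    svm_rbf = fit_svm_rbf, svm_linear = fit_svm_linear,
    logistic = fit_logistic, decision_tree = fit_tree, knn = fit_knn,
    gaussian_nb = fit_gnb, random_forest = fit_rf,
    mlp = function(...) fit_mlp_baseline(..., width = mlp_width)
  )
  rows <- imap_dfr(fits, function(f, name) {
    res <- withr::with_seed(derive_seed(seed, name), f(Xtr, ytr, Xte, Xtreat))
    rep <- classifier_report(name, res$hyperparameters, yte, res$pred, classes)
    if (!is.null(Xtreat)) {
      rep$treated_as_control_pct <- 100 * mean(res$pred_treated == "HET")
    }
    attr(rep, "per_class")$model <- name
    rep
  })
  if (isTRUE(include_feature_net)) {
    cfg <- feature_net_config %||%
      feature_net_config(input_dim = ncol(X), seed = derive_seed(seed, "feature_net"))
    cfg$input_dim <- ncol(X)
    net <- train_feature_net(traces, split, cfg)
    rep <- net$report
    if (!is.null(Xtreat) && length(classes) == 2L && "HET" %in% classes) {
      rep$treated_as_control_pct <- transfer_fraction_control(net, Xtreat)
    }
    rows <- bind_rows(rows, rep)
    attr(rows, "feature_net") <- net
  }
  rows
}

fit_svm_rbf <- function(Xtr, ytr, Xte, Xtreat) {
  gamma <- 1 / (ncol(Xtr) * mean((Xtr - mean(Xtr))^2))
  fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = 1, gamma = gamma, scale = FALSE)
  list(pred = as.character(predict(fit, Xte)),
       pred_treated = if (!is.null(Xtreat)) as.character(predict(fit, Xtreat)),
       hyperparameters = "C=1, gamma=1/(p*Var(X))")
}

fit_svm_linear <- function(Xtr, ytr, Xte, Xtreat) {
  fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = 1, scale = FALSE)
  list(pred = as.character(predict(fit, Xte)),
       pred_treated = if (!is.null(Xtreat)) as.character(predict(fit, Xtreat)),
       hyperparameters = "C=1, linear kernel")
}

# sklearn-style L2 logistic regression with C = 1 corresponds to ridge
# multinomial/binomial regression with lambda = 1 / (C * n_train)
fit_logistic <- function(Xtr, ytr, Xte, Xtreat) {
  fam <- if (nlevels(ytr) == 2L) "binomial" else "multinomial"
  fit <- glmnet::glmnet(Xtr, ytr, family = fam, alpha = 0,
                        lambda = 1 / nrow(Xtr), standardize = FALSE,
                        maxit = 1e6)
  pr <- function(M) as.character(predict(fit, M, type = "class")[, 1])
  list(pred = pr(Xte),
       pred_treated = if (!is.null(Xtreat)) pr(Xtreat),
       hyperparameters = "l2, C=1 (lambda=1/n)")
}

fit_tree <- function(Xtr, ytr, Xte, Xtreat) {
  df <- as.data.frame(Xtr)
  df$.y <- ytr
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        cp = 0, minsplit = 2, minbucket = 1, xval = 0,
                        maxcompete = 0, maxsurrogate = 0, maxdepth = 30))
  pr <- function(M) as.character(predict(fit, as.data.frame(M), type = "class"))
  list(pred = pr(Xte),
       pred_treated = if (!is.null(Xtreat)) pr(Xtreat),
       hyperparameters = "gini, no depth limit")
}

fit_knn <- function(Xtr, ytr, Xte, Xtreat) {
  list(pred = as.character(class::knn(Xtr, Xte, ytr, k = 5)),
       pred_treated = if (!is.null(Xtreat)) as.character(class::knn(Xtr, Xtreat, ytr, k = 5)),
       hyperparameters = "k=5, Euclidean")
}

# Gaussian naive Bayes with explicit variance smoothing (epsilon = 1e-9
# times the largest feature variance), matching the published configuration.
fit_gnb <- function(Xtr, ytr, Xte, Xtreat, var_smoothing = 1e-9) {
  classes <- levels(ytr)
  eps <- var_smoothing * max(apply(Xtr, 2L, function(v) mean((v - mean(v))^2)))
  stats_by_class <- lapply(classes, function(cl) {
    M <- Xtr[ytr == cl, , drop = FALSE]
    list(mu = colMeans(M),
         var = apply(M, 2L, function(v) mean((v - mean(v))^2)) + eps,
         logprior = log(nrow(M) / nrow(Xtr)))
  })
  predict_gnb <- function(M) {
    ll <- vapply(stats_by_class, function(s) {
      -0.5 * colSums((t(M) - s$mu)^2 / s$var) -
        0.5 * sum(log(2 * pi * s$var)) + s$logprior
    }, numeric(nrow(M)))
    classes[max.col(matrix(ll, nrow = nrow(M)), ties.method = "first")]
  }
  list(pred = predict_gnb(Xte),
       pred_treated = if (!is.null(Xtreat)) predict_gnb(Xtreat),
       hyperparameters = "priors=None, var_smoothing=1e-9")
}

fit_rf <- function(Xtr, ytr, Xte, Xtreat) {
  fit <- randomForest::randomForest(Xtr, ytr, ntree = 50,
                                    mtry = max(1L, floor(sqrt(ncol(Xtr)))))
  list(pred = as.character(predict(fit, Xte)),
       pred_treated = if (!is.null(Xtreat)) as.character(predict(fit, Xtreat)),
       hyperparameters = "n_estimators=50, gini, sqrt(p) features")
}

# One-hidden-layer ReLU perceptron trained with Adam via the internal
# engine (no early stopping, L2 penalty 1e-4, 200 epochs), mirroring the
# published configuration.
fit_mlp_baseline <- function(Xtr, ytr, Xte, Xtreat, width = 400L) {
  fit <- mlp_train(Xtr, as.integer(ytr), n_classes = nlevels(ytr),
                   hidden = width, dropout = 0, lr = 0.001,
                   batch_size = min(200L, nrow(Xtr)), max_epochs = 200,
                   patience = Inf, val_idx = NULL, l2 = 1e-4,
                   seed = sample.int(.Machine$integer.max, 1))
  pr <- function(M) levels(ytr)[max.col(mlp_forward(fit$par, M), ties.method = "first")]
  list(pred = pr(Xte),
       pred_treated = if (!is.null(Xtreat)) pr(Xtreat),
       hyperparameters = sprintf("hidden=(%d), relu+adam, alpha=1e-4", width))
}
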