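#' Feature-learning network configuration
#'
#' The feedforward architecture used for genotype classification: input
#' (one unit per frame) -> 512 ReLU units, dropout 0.5 -> 128 units whose
#' pre-activation `z2` is the learned cell embedding, ReLU, dropout 0.2 ->
#' softmax output. Trained with mini-batch cross-entropy and Adam
#' (learning rate 0.001, batch size 32) and early stopping on validation
#' accuracy with a patience of 30 epochs.
#'
#' @param input_dim Trace length in frames (1500 full trace, 600 basal-only).
#' @param hidden1,hidden2 Hidden-layer widths (defaults 512 and 128).
#' @param dropout1,dropout2 Dropout probabilities after each hidden layer
#'   (defaults 0.5 and 0.2).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 32).
#' @param patience Early-stopping patience in epochs (default 30).
#' @param max_epochs Epoch cap; early stopping normally triggers first
#'   (default 500).
#' @param val_fraction Fraction of the training set carved out (stratified)
#'   as the validation set driving early stopping; the test set is never
#'   used for stopping (default 0.1).
#' @param seed RNG seed for initialization, batching and dropout.
#'
#' @return A `feature_net_config` list.
#' @export
feature_net_config <- function(input_dim = 1500L, hidden1 = 512L, hidden2 = 128L,
                               dropout1 = 0.5, dropout2 = 0.2, lr = 0.001,
                               batch_size = 32L, patience = 30L,
                               max_epochs = 500L, val_fraction = 0.1, seed = 1L) {
  for (nm in c("input_dim", "hidden1", "hidden2", "batch_size", "max_epochs")) {
    check_scalar_number(get(nm), nm, min = 1)
  }
  check_scalar_number(dropout1, "dropout1", 0, 1 - 1e-9)
  check_scalar_number(dropout2, "dropout2", 0, 1 - 1e-9)
  check_scalar_number(lr, "lr", min = 1e-12)
  check_scalar_number(val_fraction, "val_fraction", 0, 0.5)
  structure(
    list(input_dim = as.integer(input_dim), hidden1 = as.integer(hidden1),
         hidden2 = as.integer(hidden2), dropout1 = dropout1, dropout2 = dropout2,
         lr = lr, batch_size = as.integer(batch_size),
         patience = as.integer(patience), max_epochs = as.integer(max_epochs),
         val_fraction = val_fraction, seed = as.integer(seed)),
    class = "feature_net_config"
  )
}

# Canonical class ordering: control first, then mutant, then treated, so the
# encoding (and argmax tie-breaking toward lower index) is deterministic.
canonical_classes <- function(labels) {
  canon <- c("HET", "HOM", "HOM_TREATED")
  present <- unique(as.character(labels))
  c(intersect(canon, present), sort(setdiff(present, canon)))
}

#' Train the feature-learning network
#'
#' Fits the network of [feature_net_config()] on the training cells of a
#' stratified split and evaluates accuracy and macro-F1 on the held-out test
#' cells. A stratified validation subset of the training cells drives early
#' stopping; the weights with the best validation accuracy are retained.
#'
#' @param traces A [trace_matrix()].
#' @param split A [stratified_split()] over the same cells.
#' @param config A [feature_net_config()]; its `input_dim` must equal the
#'   trace length.
#'
#' @return A `feature_net` object; see [glance.feature_net()] and
#'   [tidy.feature_net()] for report accessors.
#' @export
train_feature_net <- function(traces, split, config = feature_net_config()) {
  stopifnot(inherits(traces, "trace_matrix"), inherits(split, "split_spec"))
  X <- traces$values
  if (ncol(X) != config$input_dim) {
    abort(sprintf("config$input_dim = %d but traces have %d frames.",
                  config$input_dim, ncol(X)))
  }
  classes <- canonical_classes(traces$meta$group[split$train])
  if (length(classes) < 2L) abort("Training set must contain at least 2 classes.")
  y <- match(traces$meta$group, classes)
  if (anyNA(y[c(split$train, split$test)])) {
    abort("Test set contains classes absent from the training set.")
  }

  # stratified validation carve-out from the training rows (never the test set)
  val_rows <- integer(0)
  if (config$val_fraction > 0) {
    val_split <- stratified_split(traces$meta$group[split$train],
                                  test_fraction = config$val_fraction,
                                  seed = config$seed + 1L)
    val_rows <- split$train[val_split$test]
  }
  fit <- mlp_train(
    X[c(setdiff(split$train, val_rows), val_rows), , drop = FALSE] |> unname(),
    y[c(setdiff(split$train, val_rows), val_rows)],
    n_classes = length(classes),
    hidden = c(config$hidden1, config$hidden2),
    dropout = c(config$dropout1, config$dropout2),
    lr = config$lr, batch_size = config$batch_size,
    max_epochs = config$max_epochs, patience = config$patience,
    val_idx = if (length(val_rows)) seq.int(length(split$train) - length(val_rows) + 1L,
                                            length(split$train)) else NULL,
    seed = config$seed
  )

  model <- structure(
    list(par = fit$par, classes = classes, config = config,
         history = fit$history, best_epoch = fit$best_epoch,
         val_accuracy = fit$val_accuracy),
    class = "feature_net"
  )
  truth <- traces$meta$group[split$test]
  pred <- predict(model, X[split$test, , drop = FALSE])
  model$report <- classifier_report("feature_net", "1500-512-128 relu, dropout 0.5/0.2, adam lr=0.001",
                                    truth, pred, classes)
  model
}

#' @export
print.feature_net <- function(x, ...) {
  cat(sprintf("<feature_net> %s; classes: %s\n",
              paste(x$config[c("input_dim", "hidden1", "hidden2")], collapse = "-"),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  best epoch %d (validation accuracy %.3f)\n",
              x$best_epoch, x$val_accuracy))
  if (!is.null(x$report)) {
    cat(sprintf("  test accuracy %.2f%%, macro F1 %.3f\n",
                x$report$accuracy, x$report$f1_macro))
  }
  invisible(x)
}

#' Predict classes or probabilities from a trained network
#'
#' Deterministic forward pass with dropout disabled.
#'
#' @param object A `feature_net`.
#' @param newdata A [trace_matrix()] or numeric matrix of traces.
#' @param type `"class"` (default), `"prob"`, or `"z2"` for the 128-d
#'   pre-activation embedding.
#' @param ... Ignored.
#' @export
predict.feature_net <- function(object, newdata, type = c("class", "prob", "z2"), ...) {
  type <- match.arg(type)
  X <- as_trace_values(newdata)
  if (ncol(X) != object$config$input_dim) {
    abort(sprintf("Input has %d frames but the model expects %d.",
                  ncol(X), object$config$input_dim))
  }
  fw <- mlp_forward(object$par, unname(X), dropout = NULL, keep = TRUE)
  switch(type,
    prob = { colnames(fw$prob) <- object$classes; fw$prob },
    z2 = fw$Z[[2]],
    class = object$classes[max.col(fw$prob, ties.method = "first")]
  )
}

#' Hidden-layer feature embedding
#'
#' The 128-dimensional pre-activation output of the second hidden layer
#' (`z2`), a learned embedding of each cell's calcium response, computed
#' with dropout disabled.
#'
#' @param model A trained `feature_net`.
#' @param traces A [trace_matrix()] or matrix with matching frame count.
#' @return Numeric cells x 128 matrix; rownames are cell ids when available.
#' @export
extract_features <- function(model, traces) {
  stopifnot(inherits(model, "feature_net"))
  X <- as_trace_values(traces)
  z2 <- predict(model, X, type = "z2")
  rownames(z2) <- rownames(X)
  z2
}

#' Fraction of rescued cells classified as control
#'
#' Passes cells from a treatment group the model never saw through a binary
#' control/mutant classifier and reports the percentage assigned to the
#' control (HET) class — the transfer statistic used to quantify
#' pharmacological rescue.
#'
#' @param model A binary `feature_net` trained on HET vs HOM.
#' @param treated_traces A [trace_matrix()] (or matrix) of treated cells.
#' @return Percentage in `[0, 100]`.
#' @export
transfer_fraction_control <- function(model, treated_traces) {
  stopifnot(inherits(model, "feature_net"))
  if (length(model$classes) != 2L || !"HET" %in% model$classes) {
    abort("Transfer evaluation requires a binary model with a HET class.")
  }
  pred <- predict(model, treated_traces)
  100 * mean(pred == "HET")
}

# ---- classification metrics ----------------------------------------------

# accuracy (%), macro F1 and per-class precision/recall from truth/pred
classification_metrics <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- classes %||% sort(unique(c(truth, pred)))
  per_class <- map_dfr(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble(class = cl, n = sum(truth == cl), precision = precision,
           recall = recall, f1 = f1)
  })
  list(accuracy = 100 * mean(truth == pred),
       f1_macro = mean(per_class$f1[per_class$n > 0]),
       per_class = per_class)
}

classifier_report <- function(model, hyperparameters, truth, pred, classes = NULL) {
  m <- classification_metrics(truth, pred, classes)
  out <- tibble(model = model, hyperparameters = hyperparameters,
                accuracy = m$accuracy, f1_macro = m$f1_macro)
  attr(out, "per_class") <- m$per_class
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-class test metrics of a trained network
#'
#' @param x A `feature_net`.
#' @param ... Ignored.
#' @return Tibble `class`, `n`, `precision`, `recall`, `f1`.
#' @export
tidy.feature_net <- function(x, ...) attr(x$report, "per_class")

#' One-row summary of a trained network
#'
#' @param x A `feature_net`.
#' @param ... Ignored.
#' @return Tibble `accuracy` (%), `f1_macro`, `best_epoch`, `val_accuracy`,
#'   `n_classes`.
#' @export
glance.feature_net <- function(x, ...) {
  tibble(accuracy = x$report$accuracy, f1_macro = x$report$f1_macro,
         best_epoch = x$best_epoch, val_accuracy = x$val_accuracy,
         n_classes = length(x$classes))
}
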