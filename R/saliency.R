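#' Grad-CAM-style per-frame saliency
#'
#' Adapts gradient-weighted class activation mapping to the dense network:
#' the "feature map" is the first hidden layer's activations
#' `a_k = ReLU(z1_k)`; unit weights are the gradients
#' `alpha_k = d y_c / d a_k` of the target-class logit, and each unit's
#' weighted activation is redistributed over input frames through its
#' normalized absolute input weights
#' `w_hat[k, t] = |W1[t, k]| / sum_t |W1[t, k]|`. Per-frame relevance is
#' `r_t = ReLU(sum_k alpha_k a_k w_hat[k, t])`, max-normalized per cell to
#' `[0, 1]`. An input-gradient-times-input variant is available for
#' comparison.
#'
#' @param model A trained `feature_net` with two hidden layers.
#' @param traces A [trace_matrix()] or matrix of traces.
#' @param target_class Optional class name (single value or per-cell
#'   vector); defaults to each cell's predicted class.
#' @param method `"grad_cam"` (default) or `"input_gradient"`.
#'
#' @return A `saliency_map`: cells x frames matrix in `[0, 1]` with
#'   attributes `target_class` (per cell) and `method`.
#' @export
grad_cam_saliency <- function(model, traces, target_class = NULL,
                              method = c("grad_cam", "input_gradient")) {
  stopifnot(inherits(model, "feature_net"))
  method <- match.arg(method)
  X <- as_trace_values(traces)
  if (length(model$par$W) != 3L) {
    abort("Saliency is defined for the two-hidden-layer feature network.")
  }
  fw <- mlp_forward(model$par, unname(X), dropout = NULL, keep = TRUE)
  n <- nrow(X)
  if (is.null(target_class)) {
    target_class <- model$classes[max.col(fw$prob, ties.method = "first")]
  } else {
    target_class <- rep_len(as.character(target_class), n)
    if (!all(target_class %in% model$classes)) abort("Unknown target class.")
  }
  ci <- match(target_class, model$classes)

  A1 <- pmax(fw$Z[[1]], 0)                      # n x h1 activations
  relu2 <- fw$Z[[2]] > 0                        # n x h2
  W2 <- model$par$W[[2]]; W3 <- model$par$W[[3]]
  # alpha = d y_c / d a1 = ((relu'(z2) * W3[, c]) %*% t(W2)) rowwise
  D2 <- relu2 * t(W3[, ci, drop = FALSE])       # n x h2
  Alpha <- D2 %*% t(W2)                         # n x h1

  if (method == "grad_cam") {
    absW1 <- abs(model$par$W[[1]])              # p x h1
    denom <- colSums(absW1)
    denom[denom == 0] <- 1
    What <- sweep(absW1, 2, denom, "/")
    rel <- pmax((Alpha * A1) %*% t(What), 0)    # n x p
  } else {
    relu1 <- fw$Z[[1]] > 0
    Gx <- (Alpha * relu1) %*% t(model$par$W[[1]])
    rel <- pmax(Gx * unname(X), 0)
  }

  mx <- apply(rel, 1L, max)
  if (all(mx == 0)) warn("Saliency is zero everywhere (untrained or zero model).")
  pos <- mx > 0
  rel[pos, ] <- rel[pos, , drop = FALSE] / mx[pos]
  rownames(rel) <- rownames(X)
  structure(rel, target_class = target_class, method = method,
            class = c("saliency_map", class(rel)))
}

#' Tidy view of a saliency map
#'
#' @param x A `saliency_map`.
#' @return Tibble `cell_id`, `frame` (0-based), `relevance`.
#' @export
saliency_tibble <- function(x) {
  stopifnot(inherits(x, "saliency_map"))
  ids <- rownames(x) %||% sprintf("cell%04d", seq_len(nrow(x)))
  tibble(
    cell_id = rep(ids, each = ncol(x)),
    frame = rep.int(seq_len(ncol(x)) - 1L, nrow(x)),
    relevance = as.vector(t(unclass(x)))
  )
}

#' Saliency localization score
#'
#' Ratio of the mean relevance inside a window to the mean relevance
#' elsewhere; values above 1 mean the model's attention concentrates in
#' that window.
#'
#' @param saliency A `saliency_map`.
#' @param grid The [time_grid()] the traces were recorded on.
#' @param window Window name or `c(start, end)` (see [resolve_window]).
#' @return A single ratio.
#' @export
localization_score <- function(saliency, grid, window) {
  stopifnot(inherits(saliency, "saliency_map"))
  w <- resolve_window(grid, window)
  m <- unclass(saliency)
  cols <- window_cols(w)
  inside <- mean(m[, cols, drop = FALSE])
  outside <- mean(m[, -cols, drop = FALSE])
  if (outside == 0) Inf else inside / outside
}

#' Project all cells into the learned feature space
#'
#' Runs every cell — including groups the model was never trained on, such
#' as chaperone-treated cells — through a binary control/mutant network,
#' extracts the 128-d `z2` embeddings and projects them to 2D with
#' [embed_tsne()]. Group labels are carried through for plotting and
#' composition analysis.
#'
#' @param model A binary `feature_net` trained on HET vs HOM.
#' @param traces A [trace_matrix()] holding all cells.
#' @param perplexity,n_steps,seed Passed to [embed_tsne()].
#' @return A `trace_embedding` tibble with a `group` column.
#' @export
project_feature_space <- function(model, traces, perplexity = 30,
                                  n_steps = 1000, seed = 42) {
  stopifnot(inherits(model, "feature_net"), inherits(traces, "trace_matrix"))
  if (length(model$classes) != 2L) {
    abort("Feature-space projection expects a binary control/mutant model.")
  }
  z2 <- extract_features(model, traces)
  emb <- embed_tsne(z2, perplexity = perplexity, n_steps = n_steps, seed = seed)
  emb$group <- traces$meta$group
  emb
}
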