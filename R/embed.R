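new_embedding <- function(coords, method, params, ids = NULL, groups = NULL,
                          objective_trace = NULL) {
  out <- tibble(
    cell_id = ids %||% sprintf("row%04d", seq_len(nrow(coords))),
    dim1 = unname(coords[, 1]),
    dim2 = unname(coords[, 2])
  )
  if (!is.null(groups)) out$group <- groups
  attr(out, "method") <- method
  attr(out, "params") <- params
  attr(out, "objective_trace") <- objective_trace
  class(out) <- c("trace_embedding", class(out))
  out
}

embedding_input <- function(x) {
  m <- as_trace_values(x)
  if (is.null(rownames(m))) rownames(m) <- sprintf("row%04d", seq_len(nrow(m)))
  m
}

#' Principal-component 2D embedding
#'
#' First two principal-component scores of the mean-centered (unscaled)
#' matrix. If fewer than two non-degenerate components exist the second
#' coordinate is zero-filled with a warning.
#'
#' @param x A [trace_matrix()] or numeric matrix (rows = cells).
#' @return A `trace_embedding` tibble (`cell_id`, `dim1`, `dim2`, optional
#'   `group`) with a `method` attribute.
#' @export
embed_pca <- function(x) {
  m <- embedding_input(x)
  if (nrow(m) < 3L) abort("PCA embedding needs at least 3 points.")
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = 2L)
  coords <- pc$x
  if (ncol(coords) < 2L || pc$sdev[2] < 1e-12) {
    warn("Fewer than 2 informative components; second coordinate zero-filled.")
    coords <- cbind(coords[, 1], 0)
  }
  new_embedding(coords[, 1:2, drop = FALSE], "PCA",
                list(center = TRUE, scale = FALSE),
                ids = rownames(m), groups = trace_groups(x))
}

#' Exact t-SNE 2D embedding
#'
#' An exact O(n^2) t-distributed stochastic neighbour embedding: Gaussian
#' high-dimensional similarities calibrated per point to a target perplexity
#' and symmetrized, Student-t low-dimensional similarities, and gradient
#' descent (momentum + adaptive gains, early exaggeration) on the
#' Kullback-Leibler divergence KL(P||Q) = sum_{i != j} p_ij log(p_ij/q_ij).
#' The KL value against the unexaggerated P is recorded at every step and
#' returned as the `objective_trace` attribute (length `n_steps + 1`,
#' starting from the initial configuration).
#'
#' @param x A [trace_matrix()] or numeric matrix (rows = points).
#' @param perplexity Target perplexity (default 30). If `n - 1 <
#'   3 * perplexity` it is reduced to `(n - 1) / 3` with a warning.
#' @param n_steps Gradient-descent steps (default 1000).
#' @param seed RNG seed for the initial configuration (default 42).
#' @param learning_rate,early_exaggeration,exaggeration_steps Optimizer
#'   settings (defaults 200, 12, 250).
#' @return A `trace_embedding` tibble; see [embed_pca()].
#' @export
embed_tsne <- function(x, perplexity = 30, n_steps = 1000, seed = 42,
                       learning_rate = 200, early_exaggeration = 12,
                       exaggeration_steps = 250) {
  m <- embedding_input(x)
  n <- nrow(m)
  if (n < 5L) abort("t-SNE needs at least 5 points.")
  if (n - 1 < 3 * perplexity) {
    perplexity <- (n - 1) / 3
    warn(sprintf("Perplexity too large for %d points; reduced to %.2f.", n, perplexity))
  }
  P <- tsne_affinities(m, perplexity)
  withr::with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), ncol = 2)
  })
  fit <- tsne_descent(P, Y, n_steps, learning_rate, early_exaggeration,
                      exaggeration_steps)
  new_embedding(fit$Y, "TSNE",
                list(perplexity = perplexity, n_steps = n_steps, seed = seed,
                     learning_rate = learning_rate,
                     early_exaggeration = early_exaggeration),
                ids = rownames(m), groups = trace_groups(x),
                objective_trace = fit$kl)
}

# Symmetrized perplexity-calibrated joint probabilities p_ij.
tsne_affinities <- function(m, perplexity) {
  n <- nrow(m)
  sq <- rowSums(m^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(m)
  D[D < 0] <- 0
  diag(D) <- 0
  target <- log(perplexity)
  Pc <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0 } else {
        # Shannon entropy of the conditional distribution, in nats
        H <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(H - target) < 1e-7) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p <- w / max(sum(w), .Machine$double.eps)
    Pc[i, -i] <- p
  }
  P <- (Pc + t(Pc)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_descent <- function(P, Y, n_steps, eta, exaggeration, exag_steps) {
  n <- nrow(Y)
  gain <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  kl <- numeric(n_steps + 1)
  kl[1] <- tsne_kl(P, Y)
  for (step in seq_len(n_steps)) {
    Pe <- if (step <= exag_steps) P * exaggeration else P
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (step <= exag_steps) 0.5 else 0.8
    same_sign <- sign(grad) == sign(inc)
    gain <- ifelse(same_sign, gain * 0.8, gain + 0.2)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - eta * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    kl[step + 1] <- tsne_kl(P, Y)
  }
  list(Y = Y, kl = kl)
}

tsne_kl <- function(P, Y) {
  sq <- rowSums(Y^2)
  num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
  diag(num) <- 0
  Q <- pmax(num / sum(num), 1e-12)
  sum(P * log(P / Q)) - sum(diag(P * log(P / Q)))
}

#' UMAP 2D embedding
#'
#' Thin wrapper around the `uwot` implementation (the optimization is
#' consumed, not re-derived). If `uwot` is not installed a notice is logged
#' and `NULL` is returned so pipelines can continue.
#'
#' @param x A [trace_matrix()] or numeric matrix.
#' @param n_neighbors,min_dist UMAP parameters (defaults 15, 0.1).
#' @param seed RNG seed (default 42).
#' @return A `trace_embedding` tibble, or `NULL` when UMAP is unavailable.
#' @export
embed_umap <- function(x, n_neighbors = 15, min_dist = 0.1, seed = 42) {
  m <- embedding_input(x)
  if (nrow(m) < 10L) abort("UMAP embedding needs at least 10 points.")
  if (!requireNamespace("uwot", quietly = TRUE)) {
    inform("uwot is not installed; skipping the UMAP embedding.")
    return(NULL)
  }
  coords <- withr::with_seed(seed, {
    uwot::umap(m, n_neighbors = n_neighbors, min_dist = min_dist,
               n_threads = 1, n_sgd_threads = 0, batch = FALSE)
  })
  new_embedding(coords, "UMAP",
                list(n_neighbors = n_neighbors, min_dist = min_dist, seed = seed),
                ids = rownames(m), groups = trace_groups(x))
}

#' Final and per-step KL divergence of a t-SNE embedding
#'
#' @param embedding A `trace_embedding` from [embed_tsne()].
#' @return Numeric vector of KL values per optimization step.
#' @export
embedding_kl_trace <- function(embedding) {
  tr <- attr(embedding, "objective_trace")
  if (is.null(tr)) abort("This embedding carries no objective trace (t-SNE only).")
  tr
}
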