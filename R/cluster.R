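#' Lloyd K-means clustering
#'
#' K-means as classically stated: random selection of K initial centroids
#' (data points), alternating assignment (`c_i = argmin_k ||x_i - mu_k||^2`,
#' ties to the lowest cluster index) and centroid-mean update steps until
#' assignments stabilise, with the best of `n_restarts` initializations kept
#' by inertia. Empty clusters are re-seeded from the point currently
#' farthest from its centroid. Works equally on 2D embeddings and on raw
#' full-dimensional traces.
#'
#' @param x A [trace_matrix()], `trace_embedding`, or numeric matrix
#'   (rows = points).
#' @param k Number of clusters (>= 2, <= number of points).
#' @param seed RNG seed (default 42).
#' @param n_restarts Number of random initializations (default 10).
#' @param init `"random"` (random point selection, the default) or
#'   `"kmeans++"`.
#' @param max_iter Maximum Lloyd iterations per restart (default 100).
#' @param labels Optional per-point group labels; when given, the cluster
#'   composition and purity table is attached.
#' @param silhouette Compute silhouette scores (default TRUE; disable for
#'   very large inputs).
#'
#' @return A `kmeans_result` object: fields `k`, `cluster` (assignments),
#'   `centroids`, `inertia`, `inertia_trace` (per-Lloyd-iteration inertia of
#'   the winning restart), `silhouette` (per-point tibble), plus
#'   `composition` when `labels` is supplied.
#' @export
cluster_kmeans <- function(x, k, seed = 42, n_restarts = 10,
                           init = c("random", "kmeans++"), max_iter = 100,
                           labels = NULL, silhouette = TRUE) {
  if (inherits(x, "trace_embedding")) {
    labels <- labels %||% x[["group"]]
    x <- as.matrix(x[, c("dim1", "dim2")])
  }
  labels <- labels %||% trace_groups(x)
  m <- as_trace_values(x)
  n <- nrow(m)
  init <- match.arg(init)
  check_scalar_number(k, "k", min = 2)
  k <- as.integer(k)
  if (k > n) abort(sprintf("k = %d exceeds the number of points (%d).", k, n))

  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      idx <- if (init == "random") sample.int(n, k) else kmeanspp_init(m, k)
      fit <- lloyd_iterate(m, m[idx, , drop = FALSE], max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })

  sil <- NULL
  if (isTRUE(silhouette) && length(unique(best$cluster)) >= 2L) {
    sil <- silhouette_scores(m, best$cluster)
  }
  out <- structure(
    list(k = k, cluster = best$cluster, centroids = best$centroids,
         inertia = best$inertia, inertia_trace = best$trace,
         silhouette = sil, composition = NULL,
         params = list(seed = seed, n_restarts = n_restarts, init = init)),
    class = "kmeans_result"
  )
  if (!is.null(labels)) out$composition <- composition_table(best$cluster, labels)
  out
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat(sprintf("<kmeans_result> k=%d inertia=%.4g (%d Lloyd iterations)\n",
              x$k, x$inertia, length(x$inertia_trace)))
  if (!is.null(x$silhouette)) {
    cat(sprintf("  overall silhouette: %.3f\n", mean(x$silhouette$silhouette)))
  }
  if (!is.null(x$composition)) print(x$composition)
  invisible(x)
}

# squared Euclidean distances points x centroids
sqdist_to <- function(m, mu) {
  d2 <- outer(rowSums(m^2), rowSums(mu^2), "+") - 2 * tcrossprod(m, mu)
  pmax(d2, 0)
}

lloyd_iterate <- function(m, mu, max_iter) {
  n <- nrow(m)
  k <- nrow(mu)
  assign_prev <- integer(n)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- sqdist_to(m, mu)
    cl <- max.col(-d2, ties.method = "first")
    trace <- c(trace, sum(d2[cbind(seq_len(n), cl)]))
    if (identical(cl, assign_prev)) break
    assign_prev <- cl
    for (j in seq_len(k)) {
      members <- cl == j
      if (any(members)) {
        mu[j, ] <- colMeans(m[members, , drop = FALSE])
      } else {
        # re-seed an empty cluster from the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(n), cl)])
        mu[j, ] <- m[far, ]
      }
    }
  }
  list(cluster = assign_prev, centroids = mu, inertia = trace[length(trace)],
       trace = trace)
}

kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1L)) {
    d2 <- sqdist_to(m, m[idx, , drop = FALSE])
    mind <- apply(d2, 1, min)
    mind[idx] <- 0
    p <- if (sum(mind) > 0) mind / sum(mind) else rep(1 / n, n)
    idx <- c(idx, sample.int(n, 1, prob = p))
  }
  idx
}

#' Silhouette scores
#'
#' Per-point silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)`
#' the mean Euclidean distance from point `i` to the other members of its
#' cluster and `b(i)` the minimum over other clusters of the mean distance
#' to their members. Points in singleton clusters score 0.
#'
#' @param x Numeric matrix of points (or [trace_matrix()] /
#'   `trace_embedding`).
#' @param cluster Integer cluster assignment per point.
#' @return Tibble `point`, `cluster`, `silhouette`; attributes
#'   `cluster_means` (tibble) and `overall` (mean score).
#' @export
silhouette_scores <- function(x, cluster) {
  if (inherits(x, "trace_embedding")) x <- as.matrix(x[, c("dim1", "dim2")])
  m <- as_trace_values(x)
  n <- nrow(m)
  if (length(cluster) != n) abort("`cluster` length must match the number of points.")
  ks <- sort(unique(cluster))
  if (length(ks) < 2L) abort("Silhouette requires at least 2 clusters.")
  D <- as.matrix(stats::dist(m))
  s <- numeric(n)
  sizes <- table(factor(cluster, levels = ks))
  # mean distance from every point to each cluster
  mean_to <- vapply(ks, function(kk) rowSums(D[, cluster == kk, drop = FALSE]) /
                      pmax(sum(cluster == kk), 1L), numeric(n))
  for (i in seq_len(n)) {
    own <- match(cluster[i], ks)
    n_own <- sizes[[own]]
    if (n_own <= 1L) { s[i] <- 0; next }
    a <- mean_to[i, own] * n_own / (n_own - 1L)  # exclude self
    b <- min(mean_to[i, -own])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  out <- tibble(point = seq_len(n), cluster = cluster, silhouette = s)
  attr(out, "cluster_means") <- out |>
    group_by(.data$cluster) |>
    summarise(silhouette = mean(.data$silhouette), .groups = "drop")
  attr(out, "overall") <- mean(s)
  out
}

#' Cluster composition and purity
#'
#' Row-normalized group fractions per cluster; purity is the largest
#' fraction in the row.
#'
#' @param cluster Integer cluster assignment per point.
#' @param labels Group label per point.
#' @return Tibble with one row per cluster: `cluster`, `n`, one fraction
#'   column per group, and `purity`.
#' @export
composition_table <- function(cluster, labels) {
  if (length(cluster) != length(labels)) {
    abort("`cluster` and `labels` must have the same length.")
  }
  tab <- table(cluster, labels)
  frac <- prop.table(tab, margin = 1)
  out <- as_tibble(as.data.frame.matrix(frac), rownames = "cluster")
  out$cluster <- as.integer(out$cluster)
  out <- out |> mutate(n = as.integer(rowSums(tab)), .after = "cluster")
  out$purity <- unname(apply(frac, 1, max))
  out
}
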