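test_that("silhouette matches hand values, brute force, and cluster::silhouette", {
  # worked 1D example: {0,1} vs {10,11}
  m <- matrix(c(0, 1, 10, 11), ncol = 1)
  cl <- c(1L, 1L, 2L, 2L)
  s <- silhouette_scores(m, cl)
  expect_equal(s$silhouette[1], (10.5 - 1) / 10.5, tolerance = 1e-12)

  set.seed(42)
  pts <- matrix(rnorm(50 * 3), ncol = 3)
  cls <- sample(1:3, 50, replace = TRUE)
  s2 <- silhouette_scores(pts, cls)
  expect_equal(s2$silhouette, brute_silhouette(pts, cls), tolerance = 1e-9)
  expect_true(all(s2$silhouette >= -1 & s2$silhouette <= 1))
  if (requireNamespace("cluster", quietly = TRUE)) {
    ref <- cluster::silhouette(cls, stats::dist(pts))
    expect_equal(s2$silhouette, unname(ref[, "sil_width"]), tolerance = 1e-9)
  }

  # two coincident clusters: overall score <= 0
  co <- rbind(pts[1:10, ], pts[1:10, ])
  s3 <- silhouette_scores(co, rep(1:2, each = 10))
  expect_lte(attr(s3, "overall"), 0)

  expect_error(silhouette_scores(pts, rep(1L, 50)), "2 clusters")
})

test_that("Lloyd K-means recovers blobs, has monotone inertia, matches brute force", {
  m <- blob_matrix(n_per = 10, d = 2, seed = 3)
  km <- cluster_kmeans(m, 2, seed = 1)
  expect_equal(blob_agreement(km$cluster, n_per = 10), 1)
  expect_true(all(diff(km$inertia_trace) <= 1e-8))

  # K = n: one point per cluster, zero inertia
  km_n <- cluster_kmeans(m[1:5, ], 5, seed = 1)
  expect_equal(km_n$inertia, 0)

  # n = 6 points in 1D: compare against exhaustive 2-partition optimum
  x <- matrix(c(-3.1, -2.9, -0.2, 0.1, 2.8, 3.3), ncol = 1)
  best <- Inf
  for (mask in 1:(2^6 - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:5)))
    if (!any(g) || all(g)) next
    inertia <- sum((x[g] - mean(x[g]))^2) + sum((x[!g] - mean(x[!g]))^2)
    best <- min(best, inertia)
  }
  km6 <- cluster_kmeans(x, 2, seed = 2, n_restarts = 10)
  expect_equal(km6$inertia, best, tolerance = 1e-9)

  expect_error(cluster_kmeans(m[1:3, ], 5), "exceeds")
  expect_error(cluster_kmeans(m, 1), "k")
})

test_that("package K-means matches stats::kmeans on an easy instance", {
  m <- blob_matrix(n_per = 25, d = 4, seed = 9)
  km <- cluster_kmeans(m, 2, seed = 5)
  ref <- stats::kmeans(m, 2, nstart = 5)
  expect_equal(km$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("kmeans++ initialization is available and seeded", {
  m <- blob_matrix(n_per = 15, d = 2, seed = 4)
  a <- cluster_kmeans(m, 2, seed = 7, init = "kmeans++")
  b <- cluster_kmeans(m, 2, seed = 7, init = "kmeans++")
  expect_identical(a$cluster, b$cluster)
  expect_equal(blob_agreement(a$cluster, n_per = 15), 1)
})

test_that("composition tables are row-normalized with correct purity", {
  comp <- composition_table(c(1, 1, 1, 1, 2, 2), c("HET", "HET", "HET", "HOM", "HOM", "HOM"))
  expect_equal(comp$purity[comp$cluster == 1], 0.75)
  expect_equal(comp$HET[comp$cluster == 1], 0.75)
  expect_equal(comp$HOM[comp$cluster == 1], 0.25)
  expect_equal(comp$purity[comp$cluster == 2], 1)

  set.seed(11)
  cl <- sample(1:4, 200, replace = TRUE)
  lab <- sample(c("HET", "HOM", "HOM_TREATED"), 200, replace = TRUE)
  comp2 <- composition_table(cl, lab)
  fractions <- as.matrix(comp2[, c("HET", "HOM", "HOM_TREATED")])
  expect_equal(unname(rowSums(fractions)), rep(1, 4), tolerance = 1e-9)
  expect_error(composition_table(cl, lab[-1]), "length")
})
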