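test_that("PCA embedding matches an SVD oracle and preserves row order", {
  set.seed(1)
  m <- matrix(rnorm(10 * 40), nrow = 10)
  emb <- embed_pca(m)
  cm <- sweep(m, 2, colMeans(m))
  sv <- svd(cm)
  oracle <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  got <- cbind(emb$dim1, emb$dim2)
  # equal up to per-axis sign
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(got[, j], oracle[, j], tolerance = 1e-8)) ||
                isTRUE(all.equal(got[, j], -oracle[, j], tolerance = 1e-8)))
  }

  # duplicated rows embed identically
  dup <- rbind(m, m)
  e2 <- embed_pca(dup)
  expect_equal(e2$dim1[1:10], e2$dim1[11:20])

  # 2D mean-centered data with diagonal covariance: coords equal input up to
  # sign/order of axes
  x2 <- cbind(c(-2, -1, 0, 1, 2), c(0.5, -0.5, 0, -0.5, 0.5))
  x2 <- sweep(x2, 2, colMeans(x2))
  e3 <- embed_pca(x2)
  expect_equal(sort(abs(c(e3$dim1, e3$dim2))), sort(abs(as.vector(x2))),
               tolerance = 1e-8)

  expect_error(embed_pca(m[1:2, ]), "3 points")
  expect_warning(embed_pca(matrix(rep(1:5, 3), ncol = 3) + 0), "zero-filled")
})

test_that("exact t-SNE descends its KL objective and is deterministic", {
  m <- blob_matrix(n_per = 30, d = 5, seed = 2)
  a <- embed_tsne(m, n_steps = 400, seed = 42)
  b <- embed_tsne(m, n_steps = 400, seed = 42)
  expect_equal(a$dim1, b$dim1)
  kl <- embedding_kl_trace(a)
  expect_length(kl, 401)
  expect_lt(kl[length(kl)], kl[1])
  expect_true(all(is.finite(c(a$dim1, a$dim2))))
  expect_error(embed_tsne(m[1:4, ]), "5 points")
  expect_warning(embed_tsne(m[1:20, ], perplexity = 30, n_steps = 10), "reduced")
})

test_that("t-SNE separates well-separated blobs for K-means recovery", {
  ok <- 0
  for (s in 1:3) {
    m <- blob_matrix(n_per = 50, d = 10, seed = s)
    emb <- embed_tsne(m, seed = 42, n_steps = 500)
    km <- cluster_kmeans(emb, 2, seed = s)
    if (blob_agreement(km$cluster) >= 0.99) ok <- ok + 1
  }
  expect_equal(ok, 3)
})

test_that("t-SNE perplexity calibration matches an independent implementation", {
  skip_if_not_installed("Rtsne")
  m <- blob_matrix(n_per = 40, d = 8, seed = 6)
  mine <- embed_tsne(m, perplexity = 20, n_steps = 600, seed = 42)
  ref <- Rtsne::Rtsne(m, perplexity = 20, theta = 0, max_iter = 600,
                      check_duplicates = FALSE)
  km_mine <- cluster_kmeans(mine, 2, seed = 1)
  km_ref <- cluster_kmeans(ref$Y, 2, seed = 1)
  # both embeddings must expose the same 2-cluster structure
  expect_equal(blob_agreement(km_mine$cluster, 40), 1)
  expect_equal(blob_agreement(km_ref$cluster, 40), 1)
})

test_that("UMAP wrapper is deterministic and recovers blob structure", {
  skip_if_not_installed("uwot")
  m <- blob_matrix(n_per = 30, d = 10, seed = 8)
  a <- embed_umap(m, seed = 11)
  b <- embed_umap(m, seed = 11)
  expect_equal(nrow(a), 60)
  expect_equal(a$dim1, b$dim1)
  km <- cluster_kmeans(a, 2, seed = 1)
  expect_gte(blob_agreement(km$cluster, 30), 0.99)
  expect_error(embed_umap(m[1:5, ]), "10 points")
})
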