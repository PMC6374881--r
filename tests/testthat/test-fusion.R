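test_that("mean_pool averages code columns", {
  expect_equal(mean_pool(rbind(c(1, 2), c(3, 4))), c(2, 3))
  expect_equal(mean_pool(matrix(c(5, 7), 1)), c(5, 7))
  expect_equal(mean_pool(rbind(c(1, 0), c(-1, 0))), c(0, 0))
  expect_equal(mean_pool(rbind(c(1, 0), c(-1, 0)), absolute = TRUE), c(1, 0))
})

test_that("max_pool keeps the largest-magnitude signed entry per column", {
  expect_equal(max_pool(rbind(c(1, -5), c(-3, 4))), c(-3, -5))
})

test_that("mean_pool is invariant under fragment order", {
  withr::with_seed(3, {
    U <- matrix(rnorm(40), 8, 5)
    expect_equal(mean_pool(U), mean_pool(U[sample(8), ]))
  })
})

test_that("multilayer_encode concatenates pooled blocks per dictionary", {
  seqn <- random_fragment(30)
  i1 <- generate_planted_instance(K = 4, t0 = 2, n_samples = 1, seed = 1)
  i2 <- generate_planted_instance(K = 6, t0 = 2, n_samples = 1, seed = 2)

  v1 <- multilayer_encode(seqn, 10, list(i1$dictionary), t0 = 2)
  expect_length(v1, 4)

  v <- multilayer_encode(seqn, 10, list(i1$dictionary, i2$dictionary), t0 = 2)
  expect_length(v, 10)
  expect_equal(v[1:4], v1)    # block 1 depends only on dictionary 1

  # duplicated dictionary gives identical blocks
  vdup <- multilayer_encode(seqn, 10, list(i1$dictionary, i1$dictionary),
                            t0 = 2)
  expect_equal(vdup[1:4], vdup[5:8])

  # changing dictionary 2 leaves block 1 untouched
  i3 <- generate_planted_instance(K = 6, t0 = 2, n_samples = 1, seed = 9)
  v2 <- multilayer_encode(seqn, 10, list(i1$dictionary, i3$dictionary),
                          t0 = 2)
  expect_equal(v2[1:4], v[1:4])
  expect_false(isTRUE(all.equal(v2[5:10], v[5:10])))
})

test_that("fuse_dataset preserves dataset order and width", {
  ds <- two_class_dataset(count = 3L)
  dicts <- list(generate_planted_instance(3, 1, 1, seed = 1)$dictionary,
                generate_planted_instance(5, 1, 1, seed = 2)$dictionary)
  fused <- fuse_dataset(ds, 35, dicts, t0 = 2)
  expect_equal(dim(fused$features), c(6L, 8L))
  expect_equal(fused$ids, ds$records$id)
  expect_equal(fused$labels, ds$records$label)
})

test_that("pca_fit recovers exact low-dimensional structure", {
  withr::with_seed(8, {
    # points in a 2-dim affine subspace of 150-dim space
    basis <- qr.Q(qr(matrix(rnorm(150 * 2), 150, 2)))
    coords <- matrix(rnorm(40 * 2, sd = 3), 40, 2)
    X <- coords %*% t(basis) + matrix(5, 40, 150)
    m <- pca_fit(X, 2)
    Z <- pca_transform(m, X)
    recon <- Z %*% m$components + matrix(m$mean, 40, 150, byrow = TRUE)
    expect_lt(max(abs(recon - X)), 1e-8)
  })
})

test_that("full-rank PCA is an isometry of the centered data", {
  withr::with_seed(9, {
    X <- matrix(rnorm(30 * 6), 30, 6)
    m <- pca_fit(X, 6)
    Z <- pca_transform(m, X)
    expect_equal(as.vector(dist(Z)), as.vector(dist(X)), tolerance = 1e-8)
    # components are orthonormal rows
    expect_equal(m$components %*% t(m$components), diag(6),
                 tolerance = 1e-8)
  })
})

test_that("pca_transform centers, projects, and checks shapes", {
  withr::with_seed(10, {
    X <- matrix(rnorm(20 * 5), 20, 5)
    m <- pca_fit(X, 3)
    expect_equal(dim(pca_transform(m, X)), c(20L, 3L))
    expect_equal(as.vector(pca_transform(m, colMeans(X))), rep(0, 3),
                 tolerance = 1e-10)
    # displacement along component 1 maps to coordinate (2, 0, 0)
    p <- colMeans(X) + 2 * m$components[1, ]
    expect_equal(as.vector(pca_transform(m, p)), c(2, 0, 0),
                 tolerance = 1e-8)
    expect_error(pca_transform(m, matrix(0, 2, 4)), "dimension mismatch")
  })
})

test_that("isotropic noise spreads variance evenly across components", {
  withr::with_seed(12, {
    X <- matrix(rnorm(4000 * 6), 4000, 6)
    m <- pca_fit(X, 6)
    ratios <- m$explained_variance[1:6] / sum(m$explained_variance[1:6])
    expect_lt(max(ratios) - min(ratios), 0.1)
    # and it matches the eigenvalue spread of the sample covariance
    eig <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(m$explained_variance[1:6], decreasing = TRUE), eig,
                 tolerance = 1e-8)
  })
})

test_that("pca_fit rejects an out-of-range retained dimension", {
  X <- matrix(rnorm(50), 10, 5)
  expect_error(pca_fit(X, 0), "retained_dim")
  expect_error(pca_fit(X, 6), "retained_dim")
})

test_that("PCA sign convention is deterministic", {
  withr::with_seed(14, {
    X <- matrix(rnorm(200), 40, 5)
    m <- pca_fit(X, 5)
    for (i in 1:5)
      expect_gt(m$components[i, which.max(abs(m$components[i, ]))], 0)
  })
})
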