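# standard-basis dictionary restricted to the first two coordinates
basis_dict <- function() {
  D <- diag(20)[1:2, ]
  sparse_dictionary(D)
}

test_that("omp_encode recovers exact sparse combinations", {
  d <- basis_dict()
  x <- numeric(20); x[1] <- 0.3; x[2] <- 0.2

  out <- omp_encode(d, x, t0 = 2)
  expect_equal(out$coef, c(0.3, 0.2))
  expect_lt(out$residual, 1e-12)

  # with a budget of one atom, the greedy pick is the stronger coordinate
  out1 <- omp_encode(d, x, t0 = 1)
  expect_equal(out1$coef, c(0.3, 0))
  expect_equal(out1$residual, 0.2)

  # an atom itself encodes as a one-hot coefficient vector
  inst <- generate_planted_instance(K = 4, t0 = 1, n_samples = 1, seed = 3)
  atom <- inst$dictionary$D[3, ]
  out3 <- omp_encode(inst$dictionary, atom, t0 = 2)
  expect_equal(which(out3$coef != 0), 3L)
  expect_equal(out3$coef[3], 1)
  expect_lt(out3$residual, 1e-10)
})

test_that("omp_encode matches the brute-force greedy reference", {
  withr::with_seed(11, {
    for (i in 1:60) {
      K <- sample(2:6, 1)
      t0 <- sample(1:2, 1)
      D <- matrix(rnorm(K * 20), K, 20)
      D <- D / sqrt(rowSums(D^2))
      x <- rnorm(20)
      mine <- omp_encode(D, x, t0)
      ref <- omp_reference(D, x, t0)
      expect_equal(mine$residual, ref$residual, tolerance = 1e-9)
      expect_equal(mine$coef, ref$coef, tolerance = 1e-8)
    }
  })
})

test_that("omp residual is non-increasing in the sparsity budget", {
  withr::with_seed(5, {
    D <- matrix(rnorm(8 * 20), 8, 20)
    D <- D / sqrt(rowSums(D^2))
    x <- rnorm(20)
    res <- vapply(1:8, function(t0) omp_encode(D, x, t0)$residual, numeric(1))
    expect_true(all(diff(res) <= 1e-12))
  })
})

test_that("omp with t0 = K on a spanning dictionary reconstructs exactly", {
  withr::with_seed(2, {
    inst <- generate_planted_instance(K = 20, t0 = 20, n_samples = 1,
                                      seed = 9)
    x <- rnorm(20)
    expect_lt(omp_encode(inst$dictionary, x, t0 = 20)$residual, 1e-8)
  })
})

test_that("init_dictionary selects seeded data rows, unit-normalized", {
  X <- rbind(c(3, rep(0, 19)), c(0, 4, rep(0, 18)))
  d <- init_dictionary(X, K = 2, seed = 1)
  expect_equal(sort(apply(d$D, 1, which.max)), c(1L, 2L))
  expect_equal(unname(sqrt(rowSums(d$D^2))), c(1, 1))

  expect_equal(init_dictionary(X, 2, seed = 4)$D,
               init_dictionary(X, 2, seed = 4)$D)

  # fallback: fewer distinct rows than atoms
  d3 <- init_dictionary(X[1, , drop = FALSE], K = 3, seed = 2)
  expect_equal(d3$K, 3L)
  expect_equal(unname(sqrt(rowSums(d3$D^2))), rep(1, 3), tolerance = 1e-12)
})

test_that("ksvd_learn recovers a planted orthonormal dictionary", {
  inst <- generate_planted_instance(K = 4, t0 = 1, n_samples = 40, seed = 21)
  d <- ksvd_learn(inst$X, K = 4, t0 = 1, max_iter = 20, seed = 5)
  corr <- atom_correlations(inst$dictionary$D, d$D)
  expect_true(all(corr >= 0.99))
  expect_lt(utils::tail(d$error_trace, 1), 1e-8)
})

test_that("ksvd_learn is deterministic and its error trace non-increasing", {
  inst <- generate_planted_instance(K = 4, t0 = 1, n_samples = 40, seed = 13)
  d1 <- ksvd_learn(inst$X, 4, t0 = 1, max_iter = 15, seed = 8)
  d2 <- ksvd_learn(inst$X, 4, t0 = 1, max_iter = 15, seed = 8)
  expect_identical(d1$D, d2$D)
  expect_true(all(diff(d1$error_trace) <= 1e-9))
  expect_true(all(sqrt(rowSums(d1$D^2)) > 0.999))   # no dead/zero atoms
})

test_that("ksvd_learn recovers a random unit-norm dictionary on average", {
  # noiseless 2-sparse data over 8 atoms; stochastic over 5 seeds
  means <- vapply(1:5, function(s) {
    inst <- generate_planted_instance(K = 8, t0 = 2, n_samples = 400,
                                      seed = 100 + s, orthonormal = FALSE)
    d <- ksvd_learn(inst$X, 8, t0 = 2, max_iter = 12, seed = s)
    mean(atom_correlations(inst$dictionary$D, d$D))
  }, numeric(1))
  expect_gte(mean(means), 0.95)
})

test_that("ksvd_learn validates its inputs", {
  X <- matrix(rnorm(100), 5, 20)
  expect_error(ksvd_learn(X, K = 0, t0 = 1), "K")
  expect_error(ksvd_learn(X, K = 2, t0 = 0), "t0")
  expect_error(ksvd_learn(matrix(0, 5, 20), K = 2, t0 = 1), "zero")
  expect_warning(ksvd_learn(X, K = 8, t0 = 1, max_iter = 2, seed = 1),
                 "fewer training rows")
})

test_that("encode_sequence codes row-wise under the sparsity contract", {
  inst <- generate_planted_instance(K = 5, t0 = 2, n_samples = 1, seed = 4)
  V <- matrix(rep(inst$X[1, ], 3), 3, byrow = TRUE)
  codes <- encode_sequence(inst$dictionary, V, t0 = 2)
  expect_equal(codes$U[1, ], codes$U[2, ])
  expect_equal(codes$U[1, ], codes$U[3, ])
  expect_true(all(rowSums(codes$U != 0) <= 2))

  # rows that are atoms come back one-hot with unit coefficient
  codes2 <- encode_sequence(inst$dictionary, inst$dictionary$D, t0 = 2)
  expect_equal(unname(codes2$U), diag(5), tolerance = 1e-10)
  expect_true(all(codes2$residuals < 1e-10))
})

test_that("dictionary atoms must be unit norm", {
  expect_error(sparse_dictionary(matrix(2, 1, 20)), "unit")
})
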