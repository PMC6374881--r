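#' Construct a sparse dictionary object
#'
#' @param D Numeric matrix, K atoms as rows, each of dimension 20 and
#'   unit Euclidean norm.
#' @param t0 Sparsity level used / intended for encoding.
#' @param iterations Training iterations performed (0 for an untrained
#'   initialization).
#' @param seed Seed the dictionary was produced under.
#' @param error_trace Per-iteration total reconstruction error
#'   `||X - U D||_F` recorded during training, if any.
#' @return Object of class `"sparse_dictionary"`.
#' @export
sparse_dictionary <- function(D, t0 = NA_integer_, iterations = 0L,
                              seed = NA_integer_, error_trace = numeric(0)) {
  stopifnot(is.matrix(D), nrow(D) >= 1L)
  norms <- sqrt(rowSums(D^2))
  if (any(abs(norms - 1) > 1e-9))
    stop("dictionary atoms must have unit Euclidean norm")
  structure(list(D = D, K = nrow(D), t0 = t0, iterations = iterations,
                 seed = seed, error_trace = error_trace),
            class = "sparse_dictionary")
}

#' @export
print.sparse_dictionary <- function(x, ...) {
  cat("Sparse dictionary: K =", x$K, "atoms of dimension", ncol(x$D),
      "| t0 =", x$t0, "| iterations =", x$iterations, "\n")
  if (length(x$error_trace))
    cat("final reconstruction error:",
        format(utils::tail(x$error_trace, 1)), "\n")
  invisible(x)
}

#' Initialize a dictionary from data rows
#'
#' Atoms are K distinct non-zero rows of `X`, drawn under `seed` and
#' normalized to unit length; if fewer distinct non-zero rows exist, the
#' remainder are seeded random unit vectors.
#'
#' @param X Numeric data matrix (rows are samples).
#' @param K Number of atoms.
#' @param seed Integer seed.
#' @return A [sparse_dictionary()].
#' @export
init_dictionary <- function(X, K, seed = 1L) {
  stopifnot(is.matrix(X), K >= 1L)
  nz <- X[rowSums(abs(X)) > 0, , drop = FALSE]
  if (nrow(nz) == 0L) stop("X has no non-zero row")
  uniq <- nz[!duplicated(nz), , drop = FALSE]
  with_seed(seed, {
    take <- min(K, nrow(uniq))
    idx <- sample.int(nrow(uniq), take)
    D <- uniq[idx, , drop = FALSE]
    if (take < K) {
      extra <- matrix(stats::rnorm((K - take) * ncol(X)), K - take, ncol(X))
      D <- rbind(D, extra)
    }
    D <- D / sqrt(rowSums(D^2))
    dimnames(D) <- NULL
    sparse_dictionary(D, seed = seed)
  })
}

#' Orthogonal matching pursuit encoding of one vector
#'
#' Greedy sparse approximation: at each step the atom with the largest
#' absolute inner product with the current residual is added to the
#' support, coefficients of all selected atoms are refit by least squares,
#' and the residual is updated.  Stops after `t0` atoms or when the
#' residual norm falls to `tol`.
#'
#' @param dictionary A [sparse_dictionary()] or a K x d atom matrix.
#' @param x Numeric vector to encode (length = atom dimension).
#' @param t0 Maximum number of non-zero coefficients.
#' @param tol Residual norm at which to stop early (default 1e-10).
#' @return List with `coef` (length-K sparse coefficient vector) and
#'   `residual` (Euclidean norm of `x - D' u`).
#' @export
omp_encode <- function(dictionary, x, t0, tol = 1e-10) {
  D <- if (inherits(dictionary, "sparse_dictionary")) dictionary$D else dictionary
  stopifnot(is.matrix(D), length(x) == ncol(D), t0 >= 1L, t0 <= nrow(D))
  K <- nrow(D)
  u <- numeric(K)
  support <- integer(0)
  r <- x
  coef <- numeric(0)
  repeat {
    if (sqrt(sum(r^2)) <= tol || length(support) >= t0) break
    scores <- abs(drop(D %*% r))
    scores[support] <- -Inf
    j <- which.max(scores)
    A <- t(D[c(support, j), , drop = FALSE])      # d x (|S|+1)
    qrA <- qr(A)
    if (qrA$rank < ncol(A)) {
      warning("rank-deficient OMP support; stopping early")
      break
    }
    support <- c(support, j)
    coef <- qr.coef(qrA, x)
    r <- x - drop(A %*% coef)
  }
  u[support] <- coef
  list(coef = u, residual = sqrt(sum((x - drop(crossprod(D, u)[, 1]))^2)))
}

#' Sparse-code a fragment feature matrix row-wise
#'
#' @param dictionary A [sparse_dictionary()].
#' @param V Numeric matrix, rows are 20-dimensional fragment features.
#' @param t0 Sparsity level; defaults to the dictionary's own.
#' @return List of class `"sparse_codes"` with `U` (m x K coefficient
#'   matrix) and `residuals` (per-row reconstruction residual norms).
#' @export
encode_sequence <- function(dictionary, V, t0 = dictionary$t0) {
  stopifnot(inherits(dictionary, "sparse_dictionary"),
            is.matrix(V), ncol(V) == ncol(dictionary$D))
  enc <- apply(V, 1L, omp_encode, dictionary = dictionary, t0 = t0)
  structure(list(
    U = do.call(rbind, lapply(enc, `[[`, "coef")),
    residuals = vapply(enc, `[[`, numeric(1), "residual")),
    class = "sparse_codes")
}

# Frobenius reconstruction error ||X - U D||_F
.recon_error <- function(X, U, D) sqrt(sum((X - U %*% D)^2))

#' Learn an over-complete dictionary by K-SVD
#'
#' Alternating optimization: (i) with the dictionary fixed, every data
#' row is sparse-coded by OMP; (ii) with the codes fixed, each atom and
#' the coefficients that use it are updated jointly by a rank-1 SVD of
#' the residual matrix restricted to the samples using that atom.  Atoms
#' used by no sample are replaced by the worst-reconstructed data row.
#' Iteration stops at `max_iter` or when the relative decrease of the
#' total reconstruction error falls below `tol`.
#'
#' @param X Numeric matrix `N x 20` of training samples (fragment AAC
#'   vectors).
#' @param K Dictionary size (number of atoms).
#' @param t0 Sparsity level for the OMP coding step.
#' @param max_iter Maximum alternations (default 30).
#' @param seed Integer seed (initialization); results are deterministic
#'   given the seed.
#' @param tol Relative Frobenius-error decrease below which iteration
#'   stops (default 1e-4).
#' @return A trained [sparse_dictionary()] carrying the per-iteration
#'   error trace.
#' @export
ksvd_learn <- function(X, K, t0 = 5L, max_iter = 30L, seed = 1L, tol = 1e-4) {
  stopifnot(is.matrix(X))
  if (K < 1L) stop("K must be >= 1")
  if (t0 < 1L) stop("t0 must be >= 1")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (all(X == 0)) stop("X is all zero; nothing to learn")
  if (nrow(X) < K)
    warning("fewer training rows (", nrow(X), ") than atoms (", K, ")")
  D <- init_dictionary(X, K, seed)$D
  trace <- numeric(0)
  U <- NULL
  for (iter in seq_len(max_iter)) {
    enc <- apply(X, 1L, omp_encode, dictionary = D, t0 = t0)
    U <- do.call(rbind, lapply(enc, `[[`, "coef"))
    for (k in seq_len(K)) {
      used <- which(U[, k] != 0)
      if (length(used) == 0L) {
        # dead atom: replace with the currently worst-reconstructed row
        err <- rowSums((X - U %*% D)^2)
        w <- X[which.max(err), ]
        nw <- sqrt(sum(w^2))
        if (nw > 0) D[k, ] <- w / nw
        next
      }
      E <- X[used, , drop = FALSE] - U[used, -k, drop = FALSE] %*% D[-k, , drop = FALSE]
      sv <- svd(E, nu = 1L, nv = 1L)
      atom <- drop(sv$v)
      # deterministic sign: largest-magnitude loading positive
      if (atom[which.max(abs(atom))] < 0) { atom <- -atom; sv$u <- -sv$u }
      D[k, ] <- atom
      U[used, k] <- sv$d[1L] * drop(sv$u)
    }
    trace <- c(trace, .recon_error(X, U, D))
    if (iter > 1L) {
      prev <- trace[iter - 1L]
      if (prev == 0 || (prev - trace[iter]) / prev < tol) break
    }
  }
  # guard against numerically degenerate atoms
  norms <- sqrt(rowSums(D^2))
  if (any(norms == 0)) stop("zero atom after K-SVD update")
  D <- D / norms
  sparse_dictionary(D, t0 = as.integer(t0), iterations = length(trace),
                    seed = as.integer(seed), error_trace = trace)
}
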