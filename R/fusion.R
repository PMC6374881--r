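#' Mean-pool a sparse code matrix to one vector
#'
#' Collapses the m x K fragment code matrix of a sequence to a K-vector
#' of column means.  Raw signed OMP coefficients are averaged; set
#' `absolute = TRUE` to pool magnitudes instead, or use [max_pool()] for
#' the max-pooling alternative.
#'
#' @param codes A `"sparse_codes"` object from [encode_sequence()], or a
#'   plain numeric matrix of codes.
#' @param absolute Pool `|u|` instead of `u` (default `FALSE`).
#' @return Numeric vector of length K.
#' @export
mean_pool <- function(codes, absolute = FALSE) {
  U <- if (inherits(codes, "sparse_codes")) codes$U else codes
  stopifnot(is.matrix(U), nrow(U) >= 1L)
  if (absolute) U <- abs(U)
  colMeans(U)
}

#' Max-pool a sparse code matrix to one vector
#'
#' Column-wise maximum of coefficient magnitudes (signed value of the
#' largest-magnitude entry).  Provided for ablation; the pipeline default
#' is [mean_pool()].
#'
#' @inheritParams mean_pool
#' @return Numeric vector of length K.
#' @export
max_pool <- function(codes) {
  U <- if (inherits(codes, "sparse_codes")) codes$U else codes
  stopifnot(is.matrix(U), nrow(U) >= 1L)
  apply(U, 2L, function(col) col[which.max(abs(col))])
}

#' Multilayer sparse-coding feature vector of one sequence
#'
#' Encodes the sequence's fragment AAC matrix against each dictionary,
#' pools every code matrix to one vector, and concatenates the pooled
#' vectors in dictionary order.  With the default dictionary sizes 30,
#' 50 and 70 the fused vector has 150 dimensions.
#'
#' @param residues Residue string.
#' @param size,stride Sliding-window parameters.
#' @param dictionaries List of [sparse_dictionary()] objects.
#' @param t0 Sparsity level shared by all encodings; defaults to each
#'   dictionary's own `t0`.
#' @param pooling `"mean"` (pipeline default) or `"max"`.
#' @return Numeric vector of length `sum(K_i)`.
#' @export
multilayer_encode <- function(residues, size, dictionaries, stride = 1L,
                              t0 = NULL, pooling = c("mean", "max")) {
  pooling <- match.arg(pooling)
  stopifnot(length(dictionaries) >= 1L)
  V <- sequence_feature_matrix(residues, size, stride)
  pool_fun <- if (pooling == "mean") mean_pool else max_pool
  unlist(lapply(dictionaries, function(d) {
    pool_fun(encode_sequence(d, V, t0 %||% d$t0))
  }), use.names = FALSE)
}

#' Fused feature table for a whole dataset
#'
#' Applies [multilayer_encode()] to every sequence, preserving dataset
#' order.
#'
#' @param dataset A [subloc_dataset].
#' @inheritParams multilayer_encode
#' @return List with `features` (matrix `num x sum(K_i)`), `ids`,
#'   `labels`.
#' @export
fuse_dataset <- function(dataset, size, dictionaries, stride = 1L,
                         t0 = NULL, pooling = "mean") {
  stopifnot(inherits(dataset, "subloc_dataset"))
  Fm <- t(vapply(dataset$records$residues, multilayer_encode,
                 numeric(sum(vapply(dictionaries, `[[`, numeric(1), "K"))),
                 size = size, dictionaries = dictionaries, stride = stride,
                 t0 = t0, pooling = pooling, USE.NAMES = FALSE))
  list(features = Fm, ids = dataset$records$id,
       labels = dataset$records$label)
}

#' Fit a PCA model
#'
#' Mean-centered principal components by descending explained variance,
#' computed by singular value decomposition.  Component signs are fixed
#' deterministically: the largest-magnitude loading of each component is
#' made positive.
#'
#' @param x Numeric matrix `n_samples x d`.
#' @param retained_dim Number of leading components to keep.
#' @return Object of class `"pca_model"`: `mean` (length-d centering
#'   vector), `components` (`retained_dim x d`, orthonormal rows),
#'   `explained_variance` (all d singular-value variances),
#'   `retained_dim`.
#' @export
pca_fit <- function(x, retained_dim) {
  stopifnot(is.matrix(x))
  if (retained_dim < 1L || retained_dim > min(dim(x)))
    stop("retained_dim must be in 1..min(n_samples, d)")
  mu <- colMeans(x)
  Xc <- sweep(x, 2L, mu)
  sv <- svd(Xc, nu = 0L, nv = min(dim(x)))
  comps <- t(sv$v)
  for (i in seq_len(nrow(comps))) {
    if (comps[i, which.max(abs(comps[i, ]))] < 0) comps[i, ] <- -comps[i, ]
  }
  structure(list(mean = mu,
                 components = comps[seq_len(retained_dim), , drop = FALSE],
                 explained_variance = sv$d^2 / max(1L, nrow(x) - 1L),
                 retained_dim = as.integer(retained_dim)),
            class = "pca_model")
}

#' Project data onto a fitted PCA model
#'
#' @param model A `"pca_model"` from [pca_fit()].
#' @param x Numeric matrix with the model's input dimension.
#' @return Numeric matrix `n_samples x retained_dim`.
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$mean))
    stop("dimension mismatch: model expects ", length(model$mean),
         " columns, got ", ncol(x))
  sweep(x, 2L, model$mean) %*% t(model$components)
}
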