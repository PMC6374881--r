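#' Fit a multilayer sparse-coding localization model
#'
#' The central fitting function.  From a labeled sequence dataset it
#' (1) segments every sequence with a sliding window and featurizes
#' fragments by amino-acid composition, (2) learns one K-SVD dictionary
#' per entry of `K_list` from the pooled fragment features, (3) encodes
#' every sequence against every dictionary with OMP, mean-pools and
#' concatenates the codes into a fused vector of length `sum(K_list)`,
#' (4) reduces the fused features by PCA to `pca_dim` dimensions,
#' (5) optionally tops up minority classes by SMOTE, and (6) fits a
#' multiclass RBF SVM on the result.
#'
#' @param dataset A [subloc_dataset].
#' @param window_size Sliding-window size in residues; `NULL` picks 35
#'   clamped into the admissible range from [window_bounds()].
#' @param stride Window step (default 1).
#' @param K_list Dictionary sizes, stored ascending (default 30, 50, 70).
#' @param t0 OMP sparsity level (default 5 non-zeros out of 20).
#' @param max_iter,ksvd_tol K-SVD iteration budget and relative-error
#'   stopping tolerance.
#' @param pca_dim Retained PCA dimension (default 60); clamped to
#'   `min(n, sum(K_list))` with a warning.
#' @param pooling `"mean"` (default) or `"max"`.
#' @param smote `"off"` (default) or `"global"`: augment the whole
#'   PCA-reduced table before any evaluation, as when reproducing
#'   published balanced set sizes.
#' @param smote_k,smote_rounding,target_counts SMOTE options, see
#'   [balance_dataset()].
#' @param svm An [svm_config()], or `"grid"` to select one by jackknife
#'   from [default_svm_grid()].
#' @param seed Integer seed governing all randomness.
#' @return Object of class `"sparseloc_model"` with `print`, `summary`
#'   and `predict` methods; pass it to [sparseloc_jackknife()] for the
#'   leave-one-out evaluation.
#' @examples
#' ds <- generate_dataset(list(
#'   biased_profile("Cy", c("A", "L"), count = 8, length_range = c(50, 70)),
#'   biased_profile("Me", c("F", "W"), count = 8, length_range = c(50, 70))))
#' fit <- sparseloc_fit(ds, K_list = c(5, 8), t0 = 2, max_iter = 5,
#'                      pca_dim = 5)
#' fit
#' @export
sparseloc_fit <- function(dataset, window_size = NULL, stride = 1L,
                          K_list = c(30L, 50L, 70L), t0 = 5L,
                          max_iter = 30L, ksvd_tol = 1e-4,
                          pca_dim = 60L, pooling = "mean",
                          smote = c("off", "global"), smote_k = 5L,
                          smote_rounding = "half_up", target_counts = NULL,
                          svm = svm_config(), seed = 1L) {
  stopifnot(inherits(dataset, "subloc_dataset"), length(K_list) >= 1L)
  smote <- match.arg(smote)
  bounds <- window_bounds(dataset)
  if (is.null(window_size)) {
    window_size <- min(max(35L, bounds[["low"]]), bounds[["high"]])
  } else if (window_size < 1L) stop("window_size must be >= 1")
  K_list <- sort(as.integer(K_list))

  pool <- training_pool(dataset, window_size, stride)
  dictionaries <- lapply(seq_along(K_list), function(i) {
    ksvd_learn(pool$X, K_list[i], t0 = t0, max_iter = max_iter,
               seed = (seed + 1000L * i) %% .Machine$integer.max,
               tol = ksvd_tol)
  })
  fused <- fuse_dataset(dataset, window_size, dictionaries,
                        stride = stride, t0 = t0, pooling = pooling)

  d_max <- min(nrow(fused$features), ncol(fused$features))
  if (pca_dim > d_max) {
    warning("pca_dim reduced from ", pca_dim, " to ", d_max)
    pca_dim <- d_max
  }
  pca <- pca_fit(fused$features, pca_dim)
  scores <- pca_transform(pca, fused$features)

  if (smote == "global") {
    bal <- balance_dataset(scores, fused$labels, k_neighbors = smote_k,
                           seed = seed, rounding = smote_rounding,
                           target_counts = target_counts)
    scores <- bal$x
    labels <- bal$labels
    synthetic <- bal$synthetic
    ids <- c(fused$ids, sprintf("synthetic_%04d", seq_len(sum(synthetic))))
  } else {
    labels <- fused$labels
    synthetic <- rep(FALSE, nrow(scores))
    ids <- fused$ids
  }

  if (identical(svm, "grid"))
    svm <- grid_search_hyperparams(scores, labels, synthetic)
  fit <- .fit_svm(scores, labels, svm)

  structure(list(
    window = list(size = as.integer(window_size), stride = as.integer(stride),
                  bounds = bounds),
    dictionaries = dictionaries, K_list = K_list, t0 = as.integer(t0),
    pooling = pooling, pca = pca,
    features = list(fused = fused$features, scores = scores,
                    labels = labels, synthetic = synthetic, ids = ids),
    smote = list(mode = smote, k = smote_k, rounding = smote_rounding,
                 target_counts = target_counts),
    svm_config = svm, svm_fit = fit,
    class_names = dataset$class_names, seed = as.integer(seed),
    call = match.call()), class = "sparseloc_model")
}

#' @export
print.sparseloc_model <- function(x, ...) {
  cat("Multilayer sparse-coding localization model\n")
  cat("  window: size", x$window$size, "stride", x$window$stride,
      sprintf("(admissible %d..%d)\n", x$window$bounds[["low"]],
              x$window$bounds[["high"]]))
  cat("  dictionaries: K =", paste(x$K_list, collapse = ", "),
      "| t0 =", x$t0, "| pooling:", x$pooling, "\n")
  cat("  fused dimension:", sum(x$K_list), "-> PCA", x$pca$retained_dim, "\n")
  cat("  SMOTE:", x$smote$mode, "| SVM:", x$svm_config$kernel,
      "C =", x$svm_config$cost, "\n")
  cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sparseloc_model <- function(object, ...) {
  print(object)
  cat("\nTraining table:", nrow(object$features$scores), "rows (",
      sum(object$features$synthetic), "synthetic )\n")
  counts <- table(object$features$labels)
  print(counts)
  err <- vapply(object$dictionaries,
                function(d) utils::tail(d$error_trace, 1), numeric(1))
  cat("K-SVD final reconstruction errors:",
      paste(format(err, digits = 4), collapse = ", "), "\n")
  invisible(object)
}

#' Predict subcellular locations for new sequences
#'
#' @param object A fitted `"sparseloc_model"`.
#' @param newdata A [subloc_dataset], a character vector of residue
#'   strings, or a data frame with a `residues` column.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.sparseloc_model <- function(object, newdata, ...) {
  seqs <- if (inherits(newdata, "subloc_dataset")) newdata$records$residues
          else if (is.data.frame(newdata)) newdata$residues
          else as.character(newdata)
  fused <- t(vapply(seqs, multilayer_encode, numeric(sum(object$K_list)),
                    size = object$window$size, stride = object$window$stride,
                    dictionaries = object$dictionaries, t0 = object$t0,
                    pooling = object$pooling, USE.NAMES = FALSE))
  scores <- pca_transform(object$pca, fused)
  as.character(stats::predict(object$svm_fit, scores))
}

#' Jackknife evaluation of a fitted model
#'
#' `scope = "global"` reuses the model's globally fitted PCA (and any
#' SMOTE augmentation) and leave-one-out refits only the SVM — matching
#' how the published benchmark numbers are produced.  `scope = "strict"`
#' refits PCA (and reapplies SMOTE) inside every training fold so the
#' held-out sequence never influences the feature space; it is slower
#' and typically scores slightly lower, but is free of information
#' leakage.
#'
#' @param model A `"sparseloc_model"`.
#' @param scope `"global"` (default) or `"strict"`.
#' @return An `"evaluation_report"`, see [jackknife_evaluate()].
#' @export
sparseloc_jackknife <- function(model, scope = c("global", "strict")) {
  scope <- match.arg(scope)
  ft <- model$features
  if (scope == "global")
    return(jackknife_evaluate(ft$scores, ft$labels, ft$synthetic,
                              model$svm_config, ids = ft$ids))
  orig <- which(!ft$synthetic)
  fused <- ft$fused                       # original sequences only
  labels <- ft$labels[orig]
  pred <- character(length(orig))
  for (j in seq_along(orig)) {
    tr_x <- fused[-j, , drop = FALSE]
    tr_y <- labels[-j]
    pca <- pca_fit(tr_x, min(model$pca$retained_dim, min(dim(tr_x))))
    z <- pca_transform(pca, tr_x)
    syn <- rep(FALSE, nrow(z))
    if (model$smote$mode != "off") {
      bal <- balance_dataset(z, tr_y, k_neighbors = model$smote$k,
                             seed = model$seed,
                             rounding = model$smote$rounding,
                             target_counts = model$smote$target_counts)
      z <- bal$x; tr_y <- bal$labels; syn <- bal$synthetic
    }
    fit <- .fit_svm(z, tr_y, model$svm_config)
    pred[j] <- as.character(stats::predict(
      fit, pca_transform(pca, fused[j, , drop = FALSE])))
  }
  truth <- labels
  classes <- sort(unique(truth))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    cnt <- confusion_counts(truth, pred, cl)
    met <- class_metrics(cnt)
    data.frame(class = cl, t(cnt), t(met), stringsAsFactors = FALSE)
  }))
  structure(list(per_class = per_class,
                 overall_accuracy = mean(pred == truth),
                 n_scored = length(truth),
                 predictions = data.frame(id = ft$ids[orig], true = truth,
                                          predicted = pred,
                                          stringsAsFactors = FALSE),
                 config = model$svm_config), class = "evaluation_report")
}
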