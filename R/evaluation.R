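#' One-vs-rest confusion counts for one class
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param class_name The positive class.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(y_true, y_pred, class_name) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred differ in length")
  pos_t <- y_true == class_name
  pos_p <- y_pred == class_name
  c(TP = sum(pos_t & pos_p), TN = sum(!pos_t & !pos_p),
    FP = sum(!pos_t & pos_p), FN = sum(pos_t & !pos_p))
}

#' Sensitivity, specificity and Matthews correlation from counts
#'
#' `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`.
#' Any zero factor under the root (or a zero Se/Sp denominator) yields 0
#' for that metric, the standard convention for vacuous classes.
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN` as produced by
#'   [confusion_counts()].
#' @return Named numeric vector `c(Se, Sp, MCC)`.
#' @export
class_metrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  se <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  denom2 <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0
  c(Se = se, Sp = sp, MCC = mcc)
}

#' Multiclass SVM classifier configuration
#'
#' Thin wrapper around the parameters handed to [e1071::svm()] (a libsvm
#' binding; one-vs-one multiclass).  `gamma = "scale"` resolves at fit
#' time to `1 / (d * var(x))`, `gamma = NULL` to libsvm's `1/d`.
#'
#' @param kernel `"radial"` or `"linear"`.
#' @param cost Soft-margin cost C (> 0).
#' @param gamma Positive numeric, `"scale"`, or `NULL`.
#' @return A list of class `"svm_config"`.
#' @export
svm_config <- function(kernel = c("radial", "linear"), cost = 10,
                       gamma = "scale") {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0)
  structure(list(kernel = kernel, cost = cost, gamma = gamma),
            class = "svm_config")
}

.resolve_gamma <- function(gamma, x) {
  if (is.null(gamma)) return(1 / ncol(x))
  if (identical(gamma, "scale")) {
    # variance is taken after the per-column standardization the SVM fit
    # itself applies, so "scale" stays consistent with the kernel's input
    sds <- apply(x, 2L, stats::sd)
    xs <- sweep(x, 2L, ifelse(sds > 0, sds, 1), "/")
    v <- stats::var(as.vector(scale(xs, scale = FALSE)))
    return(if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x))
  }
  gamma
}

.fit_svm <- function(x, labels, config) {
  e1071::svm(x = x, y = factor(labels), kernel = config$kernel,
             cost = config$cost, gamma = .resolve_gamma(config$gamma, x),
             scale = apply(x, 2L, function(col) stats::sd(col) > 0))
}

#' Jackknife (leave-one-out) evaluation of the SVM classifier
#'
#' Every original sample is predicted by an SVM trained on all other
#' samples.  Synthetic (SMOTE) rows, when flagged, always stay in the
#' training side and are never scored, so accuracy is measured on real
#' sequences only.  Features are standardized with training-fold
#' statistics inside the SVM fit.
#'
#' @param x Numeric feature matrix.
#' @param labels Class labels, one per row.
#' @param synthetic Logical flag per row marking SMOTE rows (default:
#'   none).
#' @param config An [svm_config()].
#' @param ids Optional sequence identifiers for the prediction table.
#' @return Object of class `"evaluation_report"`: `per_class` data frame
#'   (class, TP, TN, FP, FN, Se, Sp, MCC), `overall_accuracy`, `n_scored`
#'   (= jackknife fold count), `predictions` and the config used.
#' @export
jackknife_evaluate <- function(x, labels, synthetic = NULL,
                               config = svm_config(), ids = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (is.null(synthetic)) synthetic <- rep(FALSE, nrow(x))
  scored <- which(!synthetic)
  if (length(unique(labels[scored])) < 2L)
    stop("need at least 2 classes among scored samples")
  pred <- character(length(scored))
  for (j in seq_along(scored)) {
    i <- scored[j]
    fit <- .fit_svm(x[-i, , drop = FALSE], labels[-i], config)
    pred[j] <- as.character(stats::predict(fit, x[i, , drop = FALSE]))
  }
  truth <- labels[scored]
  classes <- sort(unique(truth))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    cnt <- confusion_counts(truth, pred, cl)
    met <- class_metrics(cnt)
    data.frame(class = cl, t(cnt), t(met), stringsAsFactors = FALSE)
  }))
  structure(list(
    per_class = per_class,
    overall_accuracy = mean(pred == truth),
    n_scored = length(scored),
    predictions = data.frame(
      id = if (is.null(ids)) as.character(scored) else ids[scored],
      true = truth, predicted = pred, stringsAsFactors = FALSE),
    config = config), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("Jackknife evaluation over", x$n_scored, "samples\n")
  df <- x$per_class
  df[c("Se", "Sp", "MCC")] <- round(df[c("Se", "Sp", "MCC")], digits)
  print(df, row.names = FALSE)
  cat(sprintf("Overall accuracy (OA): %.*f\n", digits, x$overall_accuracy))
  invisible(x)
}

#' Select SVM hyperparameters by jackknife accuracy
#'
#' Evaluates each candidate configuration with [jackknife_evaluate()]
#' and returns the one with the highest overall accuracy; ties go to the
#' earliest grid entry.
#'
#' @param x,labels,synthetic As in [jackknife_evaluate()].
#' @param grid List of [svm_config()] objects; default is a small
#'   logarithmic RBF grid (C in 1/10/100, gamma in 1/d, 0.01, 0.1).
#' @return The winning [svm_config()], with the scored grid attached as
#'   attribute `"search_log"`.
#' @export
grid_search_hyperparams <- function(x, labels, synthetic = NULL,
                                    grid = default_svm_grid(ncol(x))) {
  stopifnot(length(grid) >= 1L)
  oa <- vapply(grid, function(cfg) {
    jackknife_evaluate(x, labels, synthetic, cfg)$overall_accuracy
  }, numeric(1))
  best <- grid[[which.max(oa)]]
  attr(best, "search_log") <- data.frame(
    kernel = vapply(grid, `[[`, character(1), "kernel"),
    cost = vapply(grid, `[[`, numeric(1), "cost"),
    gamma = vapply(grid, function(g) as.character(g$gamma %||% "1/d"),
                   character(1)),
    OA = oa)
  best
}

#' Default RBF hyperparameter grid
#' @param d Feature dimension (sets the `1/d` gamma entry).
#' @return List of [svm_config()] objects.
#' @export
default_svm_grid <- function(d) {
  grid <- list()
  for (cost in c(1, 10, 100))
    for (gamma in c(1 / d, 0.01, 0.1))
      grid[[length(grid) + 1L]] <- svm_config("radial", cost, gamma)
  grid
}

#' Write an evaluation report as TSV and JSON
#' @param report An `"evaluation_report"`.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @export
write_report <- function(report, tsv = NULL, json = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(tsv)) {
    utils::write.table(report$per_class, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cat(sprintf("# OA\t%.6f\n# N\t%d\n", report$overall_accuracy,
                report$n_scored), file = tsv, append = TRUE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(per_class = report$per_class,
                              overall_accuracy = report$overall_accuracy,
                              n_scored = report$n_scored),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
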