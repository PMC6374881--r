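#' Imbalance level between two classes
#'
#' Ratio of majority to minority class size; drives the SMOTE sampling
#' magnification.
#'
#' @param majority_count,minority_count Class sizes (minority >= 1).
#' @return `majority_count / minority_count`.
#' @export
imbalance_level <- function(majority_count, minority_count) {
  if (minority_count < 1) stop("minority class is empty")
  majority_count / minority_count
}

#' SMOTE sampling magnification from an imbalance level
#'
#' @param il Imbalance level (>= 1).
#' @param rounding `"half_up"` (default): round to nearest, halves up;
#'   `"ceil"`: always round up.
#' @return Integer magnification N.
#' @export
smote_magnification <- function(il, rounding = c("half_up", "ceil")) {
  rounding <- match.arg(rounding)
  stopifnot(il >= 0)
  as.integer(if (rounding == "half_up") floor(il + 0.5) else ceiling(il))
}

#' Generate synthetic minority samples by SMOTE interpolation
#'
#' Each synthetic sample interpolates between a minority sample X
#' (parents cycle round-robin over the minority rows) and one of its k
#' nearest minority neighbors y (Euclidean distance, neighbor chosen
#' uniformly): `X + r (y - X)` with `r ~ Uniform(0,1)`.
#'
#' @param minority_x Numeric matrix of minority-class feature rows
#'   (>= 2 rows).
#' @param n_synthetic Number of samples to generate (0 allowed).
#' @param k_neighbors Neighborhood size; clipped to `nrow - 1` with a
#'   warning.
#' @param seed Integer seed; fixed seed reproduces the output exactly.
#' @return List with `samples` (matrix `n_synthetic x d`), `parent`,
#'   `neighbor` (row indices into `minority_x`) and `r` (interpolation
#'   fractions).
#' @export
smote_class <- function(minority_x, n_synthetic, k_neighbors = 5L, seed = 1L) {
  stopifnot(is.matrix(minority_x))
  n <- nrow(minority_x)
  if (n < 2L) stop("SMOTE needs at least 2 minority samples")
  if (k_neighbors > n - 1L) {
    warning("k_neighbors clipped from ", k_neighbors, " to ", n - 1L)
    k_neighbors <- n - 1L
  }
  d <- as.matrix(stats::dist(minority_x))
  diag(d) <- Inf
  # k nearest neighbours of each row, ties broken by row order
  nn <- matrix(0L, n, k_neighbors)
  for (i in seq_len(n)) nn[i, ] <- order(d[i, ])[seq_len(k_neighbors)]
  out <- matrix(0, n_synthetic, ncol(minority_x))
  parent <- integer(n_synthetic); neighbor <- integer(n_synthetic)
  rr <- numeric(n_synthetic)
  with_seed(seed, {
    for (i in seq_len(n_synthetic)) {
      p <- ((i - 1L) %% n) + 1L
      y <- nn[p, sample.int(k_neighbors, 1L)]
      r <- stats::runif(1)
      out[i, ] <- minority_x[p, ] + r * (minority_x[y, ] - minority_x[p, ])
      parent[i] <- p; neighbor[i] <- y; rr[i] <- r
    }
  })
  list(samples = out, parent = parent, neighbor = neighbor, r = rr)
}

#' Balance a labeled feature table by SMOTE
#'
#' In `"auto"` mode every non-majority class c of current size n_c
#' receives `(N_c - 1) * n_c` synthetic samples, where `N_c` is the
#' rounded imbalance level against the majority class, capped so no
#' class exceeds the majority.  Explicit `target_counts` override the
#' formula per class (how published balanced set sizes are reproduced
#' exactly).  Original rows are unchanged and come first.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param labels Character vector of class labels, one per row.
#' @param k_neighbors SMOTE neighborhood size (default 5).
#' @param seed Integer seed.
#' @param rounding Rounding rule for the magnification, see
#'   [smote_magnification()].
#' @param target_counts Optional named vector `class -> final count`.
#' @return List with `x` (augmented matrix), `labels`, `synthetic`
#'   (logical flag per row) and `parents` (data frame describing each
#'   synthetic sample).
#' @export
balance_dataset <- function(x, labels, k_neighbors = 5L, seed = 1L,
                            rounding = "half_up", target_counts = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  counts <- table(labels)
  if (length(counts) < 2L) stop("need at least 2 classes to balance")
  majority <- max(counts)
  classes <- names(counts)
  add <- stats::setNames(integer(length(classes)), classes)
  for (cl in classes) {
    n_c <- as.integer(counts[[cl]])
    if (!is.null(target_counts)) {
      if (!cl %in% names(target_counts)) next
      tgt <- as.integer(target_counts[[cl]])
      if (tgt < n_c) stop("target count ", tgt, " below current size ",
                          n_c, " for class ", cl)
      add[cl] <- tgt - n_c
    } else if (n_c < majority) {
      N <- smote_magnification(imbalance_level(majority, n_c), rounding)
      add[cl] <- min((N - 1L) * n_c, majority - n_c)
    }
  }
  new_x <- list(); new_lab <- character(0)
  parents <- data.frame(class = character(0), parent = integer(0),
                        neighbor = integer(0), r = numeric(0))
  for (cl in classes[add > 0]) {
    rows <- which(labels == cl)
    syn <- smote_class(x[rows, , drop = FALSE], add[[cl]], k_neighbors,
                       # class-specific stream, kept below 2^31
                       seed = (seed + match(cl, classes) * 10007L) %% .Machine$integer.max)
    new_x[[cl]] <- syn$samples
    new_lab <- c(new_lab, rep(cl, add[[cl]]))
    parents <- rbind(parents,
                     data.frame(class = cl, parent = rows[syn$parent],
                                neighbor = rows[syn$neighbor], r = syn$r))
  }
  aug <- rbind(x, do.call(rbind, unname(new_x)))
  list(x = aug,
       labels = c(labels, new_lab),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, length(new_lab))),
       parents = parents)
}
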