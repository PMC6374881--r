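# Independent reference implementations used as oracles.  These are kept
# deliberately naive (explicit loops, lm-based least squares) and share no
# code with the package internals they check.

# Brute-force greedy sparse approximation: at every step, score each
# remaining atom by the absolute inner product with the current residual,
# take the best, and refit all selected coefficients with lm().
omp_reference <- function(D, x, t0, tol = 1e-10) {
  selected <- integer(0)
  r <- x
  coef <- numeric(0)
  for (step in seq_len(t0)) {
    if (sqrt(sum(r^2)) <= tol) break
    best <- -1; best_score <- -Inf
    for (k in seq_len(nrow(D))) {
      if (k %in% selected) next
      score <- abs(sum(D[k, ] * r))
      if (score > best_score) { best_score <- score; best <- k }
    }
    selected <- c(selected, best)
    A <- t(D[selected, , drop = FALSE])
    fit <- stats::lm.fit(A, x)
    coef <- fit$coefficients
    r <- x - as.vector(A %*% coef)
  }
  u <- numeric(nrow(D))
  u[selected] <- coef
  list(coef = u, residual = sqrt(sum((x - as.vector(t(D) %*% u))^2)))
}

# Confusion counts by explicit case-by-case enumeration.
confusion_reference <- function(y_true, y_pred, cl) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == cl && y_pred[i] == cl) tp <- tp + 1L
    else if (y_true[i] != cl && y_pred[i] != cl) tn <- tn + 1L
    else if (y_true[i] != cl && y_pred[i] == cl) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Match learned atoms to true atoms by maximal absolute correlation
# (inner product of unit vectors); returns the per-true-atom best match.
atom_correlations <- function(true_D, learned_D) {
  apply(abs(true_D %*% t(learned_D)), 1L, max)
}

# Random canonical-residue fragment.
random_fragment <- function(len) {
  paste(sample(sparseloc::AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# Small well-separated two-class dataset used across tests.
two_class_dataset <- function(count = 6L, seed = 7L) {
  generate_dataset(list(
    biased_profile("Cy", c("A", "L"), count = count,
                   length_range = c(50, 70)),
    biased_profile("Me", c("F", "W"), count = count,
                   length_range = c(50, 70))), seed = seed)
}

# Write a dataset-shaped FASTA + manifest pair into tempfiles.
write_fixture_files <- function(ids, seqs, labels, header = TRUE) {
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(paste0(">", ids, "\n", seqs), fa)
  lines <- paste0(ids, "\t", labels)
  if (header) lines <- c("id\tclass", lines)
  writeLines(lines, tsv)
  list(fasta = fa, manifest = tsv)
}
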