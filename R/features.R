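#' Admissible sliding-window sizes for a dataset
#'
#' The window size `s` must satisfy `Lmin/2 <= s <= Lmin` where `Lmin` is
#' the length of the shortest sequence in the dataset, so that even the
#' shortest sequence yields at least one full-length fragment.
#'
#' @param dataset A [subloc_dataset].
#' @return Integer vector `c(low, high)` with `low = ceiling(Lmin/2)` and
#'   `high = Lmin`.
#' @examples
#' # a dataset whose shortest sequence has 50 residues admits s in 25..50
#' @export
window_bounds <- function(dataset) {
  stopifnot(inherits(dataset, "subloc_dataset"))
  lmin <- min(nchar(dataset$records$residues))
  c(low = as.integer(ceiling(lmin / 2)), high = as.integer(lmin))
}

#' Segment a sequence with a sliding window
#'
#' Extracts every window of `size` residues, advancing by `stride`.  A
#' sequence shorter than the window is returned whole as a single
#' fragment (with a warning) rather than dropped.
#'
#' @param residues Residue string.
#' @param size Window size `s` in residues.
#' @param stride Step between window starts, default 1 (maximal overlap).
#' @return Character vector of fragments; `floor((L - size)/stride) + 1`
#'   of them when `L >= size`.
#' @export
segment_sequence <- function(residues, size, stride = 1L) {
  stopifnot(nzchar(residues), size >= 1L, stride >= 1L)
  L <- nchar(residues)
  if (L < size) {
    warning("sequence shorter than window (", L, " < ", size,
            "); emitting whole sequence as one fragment")
    return(residues)
  }
  starts <- seq.int(1L, L - size + 1L, by = stride)
  substring(residues, starts, starts + size - 1L)
}

#' Amino-acid composition of a fragment
#'
#' @param fragment Residue string over the canonical alphabet.
#' @return Numeric vector of length 20, named by [AA_ALPHABET]: the
#'   relative frequency of each amino acid.  Sums to 1.
#' @export
aac <- function(fragment) {
  stopifnot(nzchar(fragment))
  chars <- strsplit(fragment, "")[[1]]
  if (!all(chars %in% AA_ALPHABET))
    stop("non-canonical residue in fragment: ",
         paste(unique(setdiff(chars, AA_ALPHABET)), collapse = ", "))
  counts <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(as.numeric(counts) / length(chars), AA_ALPHABET)
}

#' Fragment feature matrix of one sequence
#'
#' Row i is the AAC vector of fragment i from the sliding-window
#' segmentation, so the matrix is `m x 20` with every row on the
#' 20-simplex.
#'
#' @param residues Residue string.
#' @param size,stride Window parameters, see [segment_sequence()].
#' @return Numeric matrix `m x 20` with columns named by [AA_ALPHABET].
#' @export
sequence_feature_matrix <- function(residues, size, stride = 1L) {
  frags <- segment_sequence(residues, size, stride)
  V <- t(vapply(frags, aac, numeric(20), USE.NAMES = FALSE))
  colnames(V) <- AA_ALPHABET
  V
}

#' Pool all fragment features of a dataset for dictionary learning
#'
#' Concatenates every sequence's fragment feature matrix row-wise, in
#' dataset order, into the training sample set for K-SVD.
#'
#' @param dataset A [subloc_dataset].
#' @param size,stride Window parameters.
#' @return List with `X` (numeric matrix `N x 20`, N = total fragment
#'   count) and `index` (data frame `sequence_id`, `fragment` mapping
#'   each row of `X` back to its origin).
#' @export
training_pool <- function(dataset, size, stride = 1L) {
  stopifnot(inherits(dataset, "subloc_dataset"))
  mats <- lapply(dataset$records$residues, sequence_feature_matrix,
                 size = size, stride = stride)
  m <- vapply(mats, nrow, integer(1))
  X <- do.call(rbind, mats)
  list(X = X,
       index = data.frame(sequence_id = rep(dataset$records$id, m),
                          fragment = unlist(lapply(m, seq_len)),
                          stringsAsFactors = FALSE))
}
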