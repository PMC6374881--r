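#' Define a compositional class profile for synthetic data
#'
#' Synthetic sequences carry a purely compositional class signal:
#' residues are drawn i.i.d. from `residue_weights`, which is exactly
#' the signal amino-acid-composition features can express (no motifs or
#' positional structure).
#'
#' @param class_name Label for the class.
#' @param residue_weights 20 non-negative weights over [AA_ALPHABET]
#'   summing to 1.
#' @param length_range Integer `c(min, max)` sequence length.
#' @param count Number of sequences to generate.
#' @return A list of class `"class_profile"`.
#' @export
class_profile <- function(class_name, residue_weights, length_range, count) {
  stopifnot(length(residue_weights) == 20L, all(residue_weights >= 0),
            abs(sum(residue_weights) - 1) <= 1e-9,
            length(length_range) == 2L, length_range[1] >= 1L,
            length_range[1] <= length_range[2], count >= 1L)
  structure(list(class_name = class_name,
                 residue_weights = residue_weights,
                 length_range = as.integer(length_range),
                 count = as.integer(count)),
            class = "class_profile")
}

#' A profile whose composition is concentrated on a few residues
#'
#' Convenience builder: the named `dominant` residues share `mass` of
#' the probability, the remaining residues share the rest uniformly.
#'
#' @param class_name Label.
#' @param dominant Character vector of one-letter codes to up-weight.
#' @param mass Total probability on the dominant residues (default 0.6).
#' @param length_range,count As in [class_profile()].
#' @export
biased_profile <- function(class_name, dominant, mass = 0.6,
                           length_range = c(60L, 120L), count = 20L) {
  stopifnot(all(dominant %in% AA_ALPHABET), mass > 0, mass < 1)
  w <- rep((1 - mass) / (20 - length(dominant)), 20)
  w[match(dominant, AA_ALPHABET)] <- mass / length(dominant)
  class_profile(class_name, w, length_range, count)
}

#' Generate a labeled synthetic protein dataset
#'
#' @param profiles List of [class_profile()] objects.
#' @param seed Integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return A [subloc_dataset]; ids encode class and index
#'   (`<class>_<i>`).
#' @export
generate_dataset <- function(profiles, seed = 1L) {
  stopifnot(length(profiles) >= 1L)
  with_seed(seed, {
    ids <- character(0); seqs <- character(0); labs <- character(0)
    for (p in profiles) {
      stopifnot(inherits(p, "class_profile"))
      for (i in seq_len(p$count)) {
        L <- p$length_range[1] +
          sample.int(p$length_range[2] - p$length_range[1] + 1L, 1L) - 1L
        seqs <- c(seqs, paste(sample(AA_ALPHABET, L, replace = TRUE,
                                     prob = p$residue_weights),
                              collapse = ""))
        ids <- c(ids, sprintf("%s_%03d", p$class_name, i))
        labs <- c(labs, p$class_name)
      }
    }
    subloc_dataset(ids, seqs, labs)
  })
}

#' Generate a planted sparse-coding instance
#'
#' Builds a random unit-norm (optionally orthonormal) dictionary and
#' coefficient rows with exactly `t0` non-zeros (values uniform in
#' [0.5, 1.5], seeded positions), then assembles
#' `X = U D + noise` with i.i.d. Gaussian noise of scale `noise_sigma`.
#' Serves as a recovery oracle for OMP and K-SVD.
#'
#' @param K Number of atoms (<= 20 when `orthonormal`).
#' @param t0 Non-zeros per coefficient row (<= K).
#' @param n_samples Number of data rows.
#' @param noise_sigma Additive noise scale (0 for noiseless).
#' @param seed Integer seed.
#' @param orthonormal Draw mutually orthonormal atoms (default `TRUE`).
#' @param dim Ambient dimension (default 20).
#' @return List with `dictionary` (a [sparse_dictionary()]), `U` (true
#'   coefficients), `X` (data matrix) and `noise_sigma`.
#' @export
generate_planted_instance <- function(K, t0, n_samples, noise_sigma = 0,
                                      seed = 1L, orthonormal = TRUE,
                                      dim = 20L) {
  stopifnot(t0 <= K, !orthonormal || K <= dim)
  with_seed(seed, {
    G <- matrix(stats::rnorm(dim * dim), dim, dim)
    if (orthonormal) {
      D <- t(qr.Q(qr(G))[, seq_len(K), drop = FALSE])
    } else {
      D <- G[seq_len(K), , drop = FALSE]
      D <- D / sqrt(rowSums(D^2))
    }
    U <- matrix(0, n_samples, K)
    for (i in seq_len(n_samples)) {
      supp <- sample.int(K, t0)
      U[i, supp] <- stats::runif(t0, 0.5, 1.5)
    }
    X <- U %*% D
    if (noise_sigma > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = noise_sigma),
                      nrow(X), ncol(X))
    list(dictionary = sparse_dictionary(D, t0 = as.integer(t0), seed = seed),
         U = U, X = X, noise_sigma = noise_sigma)
  })
}
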