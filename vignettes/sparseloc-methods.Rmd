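---
title: "Multilayer sparse-coding features for protein subcellular localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer sparse-coding features for protein subcellular localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseloc)
```

## The model

`sparseloc` predicts which cellular compartment a protein resides in from
its primary sequence alone. The underlying hypothesis is compositional:
proteins targeted to different compartments differ in their local
amino-acid usage, and a representation built from the composition of
short overlapping sequence windows captures this signal better than the
global composition of the whole chain.

The pipeline has six stages.

**Segmentation.** A sliding window of `size` residues (stride 1 by
default) cuts each sequence into fragments. With the shortest sequence in
the dataset of length $L_{\min}$, admissible window sizes are
$\lceil L_{\min}/2 \rceil \le s \le L_{\min}$ — wide enough to carry
composition, narrow enough that every sequence produces at least one
full window. `window_bounds()` computes the interval; for benchmark sets
whose shortest chain has 50 residues that is 25–50, and window sizes of
35–40 tend to be the accuracy plateau.

**Local features.** Each fragment maps to its amino-acid composition
(AAC): the vector of relative frequencies of the 20 canonical residues,
indexed in fixed alphabetical one-letter order (`AA_ALPHABET`). Any fixed
order works; freezing one makes dictionaries and serialized models
portable. Every AAC vector lies on the 20-simplex.

**Dictionary learning.** The pooled fragment matrix $X \in
\mathbb{R}^{N\times 20}$ trains an over-complete dictionary of $K$
unit-norm atoms by K-SVD:

$$\min_{D,U} \sum_{i=1}^N \lVert x_i - D^\top u_i \rVert_2^2
  \quad \text{s.t.} \quad \lVert u_i \rVert_0 \le T_0 .$$

The solver alternates (i) orthogonal matching pursuit (OMP) — greedily
select the atom most correlated with the residual, refit all selected
coefficients by least squares, repeat up to $T_0$ atoms — and (ii) a
rank-1 SVD update of each atom jointly with the coefficients that use it,
restricted to the samples on its support. The greedy $\ell_0$ route is
used throughout; a convex $\ell_1$ relaxation solved by LASSO would be an
alternative but is deliberately not implemented.

**Pooling and fusion.** A sequence with $m$ fragments yields an
$m \times K$ code matrix per dictionary; mean pooling collapses it to the
column-mean $K$-vector. Dictionaries of three sizes (default
$K = 30, 50, 70$) are learned independently and their pooled vectors are
concatenated, ascending in $K$, into a fused 150-dimensional feature.
Smaller dictionaries force coarse, holistic codes; larger ones resolve
finer local structure — the fusion keeps both.

**Reduction and balancing.** PCA (mean-centered SVD) reduces the fused
features, by default to 60 dimensions. Benchmark sets are imbalanced
(majority/minority ratios above 3), so SMOTE can interpolate synthetic
minority samples $P = X + r\,(y - X)$, $r \sim U(0,1)$, between a sample
and one of its $k$ nearest same-class neighbors, with magnification
$N = \mathrm{round}(\text{majority}/\text{minority})$.

**Classification and evaluation.** A multiclass SVM (libsvm via `e1071`,
one-vs-one, RBF kernel by default) is evaluated by the jackknife
(leave-one-out) test: each original sample is predicted by a model
trained on all others. The report gives one-vs-rest sensitivity
$Se = TP/(TP{+}FN)$, specificity $Sp = TN/(TN{+}FP)$ and Matthews
correlation per class, plus overall accuracy $OA = \sum_i TP_i / N$.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `window_size` | 35 (clamped into bounds) | residues per fragment; 35–40 is the empirical accuracy plateau on the apoptosis benchmarks |
| `stride` | 1 | window step in residues; stride 1 is the conventional reading of "sliding" and maximizes fragments on small sets |
| `K_list` | 30, 50, 70 | dictionary sizes (atoms); fused dimension is their sum |
| `t0` | 5 | OMP non-zeros out of 20; 25% of the input dimension is a conventional sparse-coding regime |
| `max_iter`, `ksvd_tol` | 30, 1e-4 | K-SVD stops at the iteration budget or when the relative Frobenius-error decrease falls below the tolerance |
| `pca_dim` | 60 | retained components; past the plateau extra dimensions add classifier cost without accuracy |
| `smote`, `smote_k` | off, 5 | SMOTE is opt-in; k = 5 is the canonical neighborhood, clipped to class size − 1 |
| SVM `cost`, `gamma` | 10, `"scale"` | `"scale"` resolves to $1/(d \cdot \mathrm{Var})$ of the standardized features; a small grid (`"grid"`) is available when no configuration is known |

## Design choices where the design was open

* **Stride.** Only the window-size bound is prescribed by the method;
  the step is not. Stride 1 (maximal overlap) is the default because the
  benchmark sets are small and fragments are the only training currency.
* **Sparsity level.** $T_0$ is a free parameter of the sparse-coding
  regime. The default 5 is documented as such and configurable; nothing
  in the pipeline depends on its exact value.
* **Signed pooling.** Mean pooling averages the raw signed OMP
  coefficients (a plain mean); pooling magnitudes (`absolute = TRUE`) and
  max pooling exist as ablation options only.
* **Rounding of the magnification.** "Round" glossed as "rounding up" is
  ambiguous; the default is round-half-up with a `ceil` switch. Published
  balanced set sizes that no single rounding reproduces (e.g. a class of
  17 topped up to 51 against a majority of 112) are reproduced exactly via
  explicit `target_counts`.
* **Evaluation scope.** In `"global"` scope PCA (and SMOTE) are fitted on
  the full dataset before the jackknife, matching how benchmark numbers
  are customarily produced; `"strict"` scope refits both inside every
  training fold, paying runtime for leakage hygiene. Both are first-class;
  the default is `"global"` for comparability, and the strict option makes
  the leakage cost measurable rather than hypothetical.
* **SVM hyperparameters.** No kernel or cost is prescribed anywhere for
  this task; the package defaults to RBF with $C = 10$ and `"scale"`
  gamma, and exposes a small logarithmic grid selected by jackknife
  accuracy (ties go to the first grid entry) with the search log attached
  to the result.

## Numerical choices

* Dictionary atoms are unit-norm within $10^{-9}$; K-SVD atom updates fix
  the SVD sign ambiguity by making the largest-magnitude loading
  positive, so training is bit-reproducible for a fixed seed. PCA
  components use the same sign convention.
* OMP stops early when the residual norm reaches $10^{-10}$; a
  rank-deficient selected support stops the pursuit with a warning rather
  than failing.
* Dead atoms (used by no sample after a coding pass) are replaced by the
  worst-reconstructed training row, normalized — the standard K-SVD
  robustness fix.
* Dictionary initialization draws K distinct non-zero data rows under the
  seed; if the data has fewer distinct rows, the remainder are random
  unit vectors.
* MCC with any zero factor under the root is defined as 0; Se/Sp with a
  zero denominator likewise. Sequences shorter than the window are kept
  as a single whole-sequence fragment (with a warning) instead of being
  dropped. Non-canonical residues (B, Z, X, U, O, J, `*`, gaps) are
  dropped by default with a per-record warning; a `reject` policy is
  available.
* All randomness flows through per-call integer seeds; library calls
  restore the caller's RNG state.

## What the synthetic generator does and does not emulate

`generate_dataset()` draws sequences i.i.d. from per-class residue
distributions — a purely compositional class signal, which is exactly the
signal AAC features can express. Real localization signals also live in
positional structure: N-terminal targeting peptides, transmembrane
segments, motifs. The generator deliberately contains none of these, so a
pipeline that passes the synthetic recovery tests is validated as an
implementation (segmentation, coding, fusion, classification all work)
but not as a biological predictor; benchmark accuracy on curated datasets
must be measured separately on real data. `generate_planted_instance()`
provides the complementary oracle for the sparse-coding core: data built
from a known dictionary with known sparse coefficients, optionally with
Gaussian noise, against which OMP and K-SVD recovery are checked exactly.

## Problem sizes used by the test suite

The suite validates on deliberately compact instances: dictionaries of
4–20 atoms for recovery oracles (400 samples for the stochastic
dictionary-recovery property, 5 seeds), 60-sequence 3-class sets with
dictionary sizes 10/15/20 and a K-SVD budget of 8–10 iterations for the
end-to-end jackknife check, and a reduced budget of 2 iterations where
only shapes (the 150-dimensional fusion contract) are at stake. These
sizes were chosen so every property that scales (simplex constraints,
convexity, monotone error traces, oracle equivalence) is exercised at
full strength while the suite stays quick to run.

## Known limitations

* Multi-compartment (multilabel) proteins are out of scope; every
  sequence carries exactly one class.
* Features are composition-only; no PseAAC, PSSM, GO or evolutionary
  information, so homologs with divergent localization are
  indistinguishable when their composition matches.
* Jackknife is the only first-class protocol (it is deterministic for a
  given dataset); k-fold runs would need to be assembled from the exported
  stage functions.
* Benchmark-scale accuracy depends on unstated SVM hyperparameters in the
  original experiments; identical numbers should not be expected from any
  reimplementation without the same tuning.
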