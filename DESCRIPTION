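Package: sparseloc
Title: Multilayer Sparse-Coding Features for Protein Subcellular
    Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the subcellular localization of apoptosis proteins
    from sequence alone.  Sequences are segmented with a sliding window,
    fragments are featurized by amino-acid composition, sparse-coded
    against K-SVD-learned dictionaries of several sizes via orthogonal
    matching pursuit, mean-pooled and concatenated into a fused feature
    vector, reduced by principal component analysis, optionally
    class-balanced by SMOTE interpolation, and classified with a
    multiclass support vector machine evaluated by the jackknife
    (leave-one-out) test with per-class sensitivity, specificity,
    Matthews correlation coefficient and overall accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
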