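Package: cdanpl
Title: Conditional Domain Adversarial Networks with Pseudo-Labels for Raman
    Spectral Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised domain adaptation for 1-D Raman spectra. Implements
    a pseudo-label-based conditional domain adversarial network (CDAN-PL):
    a dual-branch spectral feature extractor (self-attention encoder plus
    multi-scale 1-D convolutions), a conditional domain discriminator driven
    by the multilinear map of features and class probabilities, KNN
    pseudo-labeling with confidence filtering and decision-level fusion, and
    a Fisher-style metric-constraint loss that preserves class structure
    during adversarial alignment. Ships the standard serum-Raman
    preprocessing stack (iterative polynomial baseline correction, mean
    smoothing, min-max normalization, SMOTE balancing, PCA harmonization),
    a two-domain synthetic spectrum generator for end-to-end validation
    without clinical data, and Grad-CAM attribution with key-peak extraction
    plus t-SNE alignment exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
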