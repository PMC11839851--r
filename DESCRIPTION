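Package: SpectCertainty
Title: Label-Uncertainty-Aware Training and Conclusiveness Analysis for
    Striatal SPECT Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how multi-reader label uncertainty can be
    exploited during the training of convolutional neural networks for
    binary classification of dopamine transporter (DAT) SPECT slab
    images.  Implements three reference-standard schemes (majority-vote,
    random-vote and average-vote training), a compact single-channel
    ResNet-18 with exact parameter accounting, data-driven inconclusive
    intervals on the sigmoid output, certainty-stratified balanced
    accuracy with its area-under-curve summary, and the Nadeau-Bengio
    corrected resampled t-test.  A synthetic striatal phantom cohort
    generator with a simulated three-reader panel and
    out-of-distribution variants makes the full pipeline testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'SpectCertainty-package.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'phantom.R'
    'readers.R'
    'cohort.R'
    'aggregation.R'
    'resize.R'
    'arch.R'
    'train.R'
    'conclusive.R'
    'evaluation.R'
    'experiment.R'
    'io.R'
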