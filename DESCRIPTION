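Package: coralrhythm
Title: Activity Rhythms of Sessile Corals from Time-Lapse Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts time-lapse images of a sessile cold-water coral colony into
    per-status surface-coverage time series (bloated, semi-bloated, non-bloated,
    background) by patch-based convolutional classification over sliding windows,
    after CLAHE enhancement and HSV red-mask segmentation. The coverage series are
    analysed jointly with oceanographic records using chronobiology statistics
    (Lomb-Scargle periodogram over the 600-1620 min band, 24-h waveform analysis
    with MESOR and phase) and a shallow feed-forward network on combinatorial
    polynomial features with Bayesian-regularized training, Kennard-Stone
    Euclidean-distance partitioning and hidden-weight feature importance. Includes
    a ground-truthed synthetic fixture generator (coral-like scenes and rhythmic
    multiparametric series) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Classification, TimeCourse
RoxygenNote: 7.3.3
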