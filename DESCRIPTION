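Package: flimcyte
Title: Multispectral Multiphoton FLIM Analysis of Cellular Skin Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multispectral time-correlated single
    photon counting (TCSPC) fluorescence lifetime imaging of skin:
    simulation of FLIM image stacks and two-class patient cohorts with
    ground truth, instrument-response reconvolution fitting of mono- and
    bi-exponential decays with photon-count exclusion rules, automatic
    cell detection by a size-tuned rank-order top-hat transform,
    Gabriel-graph cellular morphology features, descriptive and
    inferential group statistics, and a PCA plus LDA leave-one-out
    diagnostic classifier with patient-level ROC evaluation for
    discriminating basal cell carcinoma from normal skin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    MASS,
    EBImage,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    minpack.lm,
    pROC,
    withr
Config/testthat/edition: 3
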