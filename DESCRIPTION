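Package: stageseg
Title: Segregating Cognitive Task Stages from Multivariate BOLD Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Supervised and unsupervised segmentation of cognitive task stages
    from multivariate fMRI BOLD region-of-interest time series. Implements
    MANOVA test statistics (Hotelling-Lawley trace, Wilks' lambda, Roy's
    greatest characteristic root) normalized by autocorrelation-preserving
    label bootstraps (block permutation, cycle shifting, random permutation),
    lag/lead alignment profiles, hypothesis-driven choice groupings contrasted
    through Mahalanobis distances, k-medoids voxel selection with regularized
    Fisher discriminant projections, and Gaussian-emission hidden Markov model
    segmentation with AIC state-count selection, Viterbi decoding and a
    Matching Index against behavioral labels. Includes a synthetic-data
    generator for self-paced multi-trial task designs with AR(1) noise and
    hemodynamic response convolution, plus Wiener deconvolution and the
    standard preprocessing chain (detrending, discrete-cosine high-pass,
    nuisance regression, control-phase subtraction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
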