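Package: oscportraits
Title: Single-Trial Oscillatory Portraits and Effective Connectivity Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-trial oscillatory "portraits":
    48-dimensional vectors of band-limited, epoch-averaged log power (4 cortical
    regions x 3 movement epochs x 4 frequency bands) extracted from trial-epoched
    neural time series via Morlet wavelet decomposition. Portraits are modelled
    with Gaussian random-intercept linear mixed models to estimate directed
    effective-connectivity networks between oscillatory elements (and, optionally,
    behavioural variables), which are characterised through weighted homophily
    with label-permutation nulls, strong-link thresholding, node strengths, and
    cross-training generalisation across trial categories. Pairwise trial-category
    discrimination (ROC/AUC with shuffle controls), single-trial behaviour
    prediction, Bhattacharyya distribution overlap, and iterative amplitude
    adjusted Fourier transform (IAAFT) surrogate generation are included, together
    with a fully parameterised synthetic-data generator with closed-form
    connectivity ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite, tools
Suggests: testthat (>= 3.0.0), lme4, pROC
Config/testthat/edition: 3
biocViews: TimeCourse, Network, Regression, Classification
RoxygenNote: 7.3.3
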