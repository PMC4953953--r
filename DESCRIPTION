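Package: eegroi
Title: Emotion Discrimination from EEG Source Imaging with Compact Regions of Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for discriminating affective states from multichannel EEG
    by imaging cortical source activity. Provides a synthetic spherical head
    model and lead-field generator, regularized distributed inverse solutions
    (a LORETA-style smoothness prior and a Multiple Sparse Priors covariance
    model with restricted-maximum-likelihood hyperparameter optimization),
    data-driven selection of spatially compact regions of interest from the
    source energy map, a 45-statistic feature set per signal (Welch band
    power, Hjorth parameters, continuous and discrete wavelet amplitudes),
    eigenvalue-based feature relevance ranking, and leave-one-out support
    vector machine evaluation with accuracy, F1 and paired one-sided t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
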