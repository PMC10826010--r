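Package: stsg
Title: Synthetic Time-Series Generation and Evaluation for Longitudinal Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates privacy-preserving synthetic counterparts of longitudinal
    health datasets that pair per-subject metadata (the static component) with
    multivariate time series (the dynamic component). Implements three
    generation strategies: synthesizing metadata and coupling it to real series
    (A1), synthesizing metadata and series separately and coupling them (A2),
    and jointly synthesizing both (A3). Ships two adversarial backends -- a
    Wasserstein GAN with gradient penalty and a correlation-alignment loss, and
    a DoppelGANger-style metadata-conditioned recurrent generator -- plus a
    fast resampling baseline, together with a tri-dimensional evaluation suite
    covering resemblance (mixed-type association matrices, data-labelling
    analysis, precision-recall distributions, autocorrelation error), utility
    (train-on-synthetic-test-on-real regression), and privacy (cosine-distance
    membership inference attacks), aggregated over pseudo-cross-validation
    folds with pairwise significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    zoo,
    stats,
    utils,
    jsonlite,
    randomForest,
    e1071,
    rpart,
    caret,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
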