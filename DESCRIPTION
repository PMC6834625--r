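Package: swayrisk
Title: Postural Sway Metrics and Random-Forest Fall-Risk Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a panel of time-domain, frequency-domain and nonlinear
    postural sway metrics from raw centre-of-pressure (COP) force-platform
    recordings, combines them with clinical balance scores (Berg Balance
    Scale, balance confidence, Physiological Profile Assessment fall-risk
    bins), and evaluates random-forest classifiers for every pairwise
    fall-risk group comparison, reporting diagnostic accuracy, sensitivity,
    specificity and Mean Decrease Impurity feature importance. Includes a
    seeded synthetic cohort generator with group-graded mediolateral sway
    amplitude and sway regularity so the full pipeline is reproducible
    without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
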