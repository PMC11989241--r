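Package: actihurst
Title: Complexity Profiling of Actigraphy via Variational Hurst Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Digital mental biomarkers from wrist-worn accelerometer recordings.
    Estimates the Hurst exponent of self-similar time series by a variational
    scaling principle on dyadic midpoint variations, projects long actigraphy
    streams to windowed complexity profiles with bipolar-disorder episode
    indexing, locates mood states as intervals between inflection points of the
    kernel density of windowed Hurst exponents and computes their probabilities,
    and extrapolates partial complexity trajectories by density matching against
    a library of fractional Gaussian noise scenarios. Includes exact
    (circulant-embedding) simulators for fractional Brownian motion and
    fractional Gaussian noise and a regime-switching synthetic actigraphy
    generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
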