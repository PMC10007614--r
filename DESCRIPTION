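Package: sorsfresh
Title: Freshness Prediction from Spatially Offset Raman Scattering Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, preprocesses and models line-scan spatially offset
    Raman scattering (SORS) images of two-layer shell-over-meat samples for
    storage-day (freshness) regression. Provides a deterministic synthetic
    data generator for raw scattering cubes, the full preprocessing chain
    (region-of-interest cropping, Stokes shift conversion, anomalous-spectrum
    removal by peak matching, cosmic-ray trimming, Savitzky-Golay smoothing,
    adjacent-band averaging and symmetric offset folding to a 200 x 11
    waveband-by-offset matrix), a many-to-one attention-based LSTM regressor
    with exact per-layer parameter accounting and structural ablations,
    optimal-offset chemometric baselines (PLSR, SVR, extremely randomized
    trees), and an evaluation protocol reporting R-squared, RMSE and
    residual prediction deviation with per-day prediction summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    mixOmics,
    purrr,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
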