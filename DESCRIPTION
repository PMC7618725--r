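Package: gaspread
Title: Gamma Activation Spread Analysis for Task MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies the regional spread of gamma-band (30-48 Hz) and
    high-gamma (52-80 Hz) activations in parcellated task MEG recordings
    during sustained grip. Implements Morlet time-frequency decomposition
    with per-trial baseline correction and 100 ms band-power binning,
    control-calibrated (+/- 2 SD) activation thresholds, region-count
    spread time courses and the gamma activation spread (GAS) summary,
    permutation-based general linear model inference with max-statistic
    family-wise error control, Welch comparisons of behavioural summaries
    with Bonferroni correction, and a synthetic cohort simulator used to
    validate every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
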