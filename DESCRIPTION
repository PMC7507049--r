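Package: racepli
Title: Race-Model Analysis of Audio-Visual Reaction Times and
    Phase-Lag-Index EEG Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying multisensory audio-visual integration from
    redundant-signals reaction-time experiments and for measuring age-related
    differences in global functional brain connectivity from multichannel EEG.
    Implements the independent race model (Miller bound) on empirical response
    CDFs with violation testing, peak benefit, peak latency and positive AUC;
    windowed-Fourier instantaneous phase extraction and the phase lag index
    (PLI) with band averaging and network-mean connectivity time series;
    pointwise group comparisons with significant-window detection and mixed
    2x2x3 ANOVA with Greenhouse-Geisser correction; and synthetic generators
    for ex-Gaussian reaction times with a controllable coactivation component
    and for coupled-oscillator EEG epochs with von Mises phase jitter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    car,
    rhdf5,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
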