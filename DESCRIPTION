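Package: cacoupling
Title: Frequency-Specific Coupling Functions Between Arterial Pressure and
    Cerebral Oxygenation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing dynamic cerebral autoregulation from
    simultaneous recordings of arterial blood pressure and near-infrared
    spectroscopy oxyhemoglobin (delta-HbO2) signals. Implements beat detection
    and mean arterial pressure extraction, despiking and zero-phase Butterworth
    filtering, continuous Morlet wavelet phase extraction in four physiological
    frequency intervals (cardiac, respiratory, myogenic, neurogenic), dynamical
    Bayesian inference of coupled phase-oscillator models with a second-order
    Fourier basis, reconstruction of coupling functions on a phase grid,
    directional coupling-strength quantification, surrogate-data significance
    testing, and channel-wise and hemispheric group statistics. A synthetic-data
    module generates ground-truth coupled oscillators, pulsatile pressure
    waveforms, and artifact-contaminated multichannel signals for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
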