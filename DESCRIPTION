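Package: stnio
Title: Aperiodic and Periodic Spectral Analysis of Subthalamic Input-Output Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intraoperative subthalamic nucleus (STN)
    microelectrode recordings in Parkinson's disease, separating local field
    potential (input) and spiking discharge rate (output) activity into
    aperiodic (1/f^alpha) and periodic (oscillatory) spectral components.
    Implements Welch spectral estimation with line-noise repair, a
    spectral-parameterization (FOOOF-style) fitter with a
    frequency-proportional peak-width bound, frequency- and time-domain
    whitening, beta center-frequency detection, alignment and bandwidth
    measurement, trajectory assembly with safe subregion boundaries, and a
    GLM layer relating predictor families to clinical burden and treatment
    efficacy. Includes a synthetic-data generator emulating the study's
    signal structure (colored-noise LFP, near-white rectified spiking rate,
    Poisson spikes riding on beta peaks) for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    data.table,
    jsonlite,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
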