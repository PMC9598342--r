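Package: ppgrr
Title: Respiration Rate Estimation from Photoplethysmogram Signals with a 1-D ConvMixer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating respiration rate (breaths per
    minute) directly from single-channel photoplethysmogram (PPG) waveforms.
    Implements zero-phase Butterworth low-pass denoising, variational mode
    decomposition (VMD) for motion-artifact removal, sliding-window
    segmentation, a lightweight 1-D ConvMixer regression network with exact
    parameter accounting, cross-validation and fine-tuning training protocols,
    and Bland-Altman style agreement statistics. Ships a synthetic PPG
    generator with respiratory-induced baseline, amplitude and frequency
    modulation so the full system can be exercised without access to clinical
    waveform databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
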