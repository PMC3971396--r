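Package: cfcpredict
Title: Preictal State Discrimination from Slow-Wave/Gamma Phase-Amplitude Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting preictal (pre-seizure) states in long-term
    multichannel intracranial EEG from cross-frequency coupling. For each
    contact the preferred ("mean coupling") phase at which gamma-band
    amplitude (40-140 Hz) nests within slow oscillations (delta 0.5-3 Hz or
    theta 3-8 Hz) is extracted in one-minute windows via zero-phase
    Butterworth filtering and the Hilbert analytic signal. The proportion of
    contacts occupying a given coupling-phase interval is smoothed with a
    causal first-order Kalman filter and thresholded to raise alarms with a
    refractory period. Includes prospective train/test evaluation
    (sensitivity and false prediction rate), statistical validation against
    a Poisson random predictor and a group-level binomial test, a Burg
    spectral band-power baseline predictor, a synthetic EEG generator with
    programmable coupling and preictal phase shifts, and minimal EDF I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
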