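Package: mfjr
Title: Multi-Frequency Jansen-Rit Whole-Brain Modelling with Homeostatic
    Inhibitory Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-brain electrophysiological and haemodynamic
    activity with a two-subpopulation (alpha/gamma) Jansen-Rit neural mass
    model extended with homeostatic inhibitory synaptic plasticity (ISP).
    Regions are coupled through a structural connectome and integrated with
    the Euler-Maruyama scheme; pyramidal firing rates drive a generalized
    Balloon-Windkessel model to produce BOLD-like signals. Includes the
    observable stack used to confront such models with data (Bessel band-pass
    filtering, Hilbert amplitude envelopes, envelope and BOLD functional
    connectivity, Welch spectra, relative band power), goodness-of-fit
    metrics (windowed structural similarity, Clarkson spectral distance,
    Cohen's d), exhaustive grid sweeps with dual EEG+fMRI masked selection,
    connectome utilities (normalization, homotopic augmentation, AAL90
    region selections, synthetic modular connectomes), and config-driven
    desk-scale experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
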