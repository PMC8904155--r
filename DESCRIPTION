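Package: rgcstim
Title: Retinal Ganglion Cell Responses to Epiretinal Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-compartment Hodgkin-Huxley style simulation of retinal
    ganglion cells (RGCs) under extracellular stimulation by a disk electrode,
    aimed at epiretinal prosthesis stimulus design. Provides biophysical
    presets for A2-monostratified and D1-bistratified RGCs, charge-balanced
    biphasic pulse-train stimuli with configurable pulse width and interphase
    gap, an analytic disk-electrode field model, a compartmental cable solver
    with an extracellular mechanism (implemented in C++), and a protocol suite:
    spike-probability threshold search, strength-duration and interphase-gap
    sweeps, rate-versus-amplitude response curves, saturation-window and
    differential-response metrics, channel-swap experiments, and refractory
    period and depolarizing-sag measurements.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
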