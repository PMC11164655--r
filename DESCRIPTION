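Package: colortag
Title: Frequency-Tagged SSVEP Analysis of Divided Attention to Color
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and analysis tools for frequency-tagged random-dot
    kinematogram experiments on feature-based attention to color: CIELCh
    stimulus colorimetry under a D65 reference white, session planning with
    coherent-motion event scheduling, signal-detection scoring (criterion c
    and d-prime) of yes/no responses, steady-state visual evoked potential
    (SSVEP) amplitude extraction at the stimulation frequencies with
    attended-minus-unattended effects, and a resource-split multiplier model
    for divided attention, together with a synthetic behavioral and EEG data
    generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, rhdf5, jsonlite, optparse
Config/testthat/edition: 3
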