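Package: memdecay
Title: Implicit-Memory Decay in Auditory Psychophysics, ERP Adaptation, and
    Oral Reading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the temporal decay of implicit memory for
    sounds and written non-words. Provides synthetic-data generators for
    two-tone frequency-discrimination trial sequences, a contraction-bias
    observer whose reliance on the stimulus prior decays with the inter-trial
    interval, single-channel EEG with planted N1/P2 adaptation-recovery
    dynamics, and self-paced oral-reading sessions with decaying repetition
    priming. Analysis routines compute signal-detection sensitivity (d'),
    Bias+/Bias- context effects, a three-predictor choice GLM, ERP component
    areas under amplitude-based artifact rejection, repetition benefits in
    reading latencies, and bounded multi-start exponential-decay fits of any
    of these measures, together with cohort-level simulation and
    nonparametric group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
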