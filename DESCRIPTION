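Package: pgti
Title: Prompt Gamma Time Imaging for Proton Range Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for prompt-gamma timing (PGT) and prompt-gamma
    time imaging (PGTI) in particle-therapy range verification. Provides a
    Bragg-Kleeman proton kinematics model for PMMA phantoms, a synthetic
    event generator emulating single-proton-regime time-of-flight (TOF)
    experiments at cyclotron and synchro-cyclotron beam lines (bunch
    occupancy, prompt-gamma emission, Cherenkov detector response, dark-count
    and bunch-structured backgrounds), event-by-event TOF-to-vertex
    reconstruction through per-detector reference time maps, the integral
    fall-off shift statistic with subsampling-bootstrap error extrapolation,
    and counting-statistics models for random coincidences, effective
    beam intensity and single-proton-regime delivery time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
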