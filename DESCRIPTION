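Package: optoflow
Title: Modular fNIRS Preprocessing, De-Noising and Activation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully scripted processing pipeline for task-based
    functional near-infrared spectroscopy (fNIRS) recordings: automated channel
    exclusion (coefficient of variation and windowed scalp-coupling-index /
    cardiac-power rules), wavelet-based motion-artifact correction, conversion
    of dual-wavelength intensities to oxy- and deoxyhemoglobin concentration
    changes via the modified Beer-Lambert law with age-dependent differential
    path length factors, three zero-phase band-pass filters, three
    low-frequency de-noising strategies (short-separation adaptive filtering,
    first-principal-component removal, and delay-corrected global-average
    regression), and a prewhitened robust general linear model with canonical
    HRF derivatives and a combined oxy/deoxy activation criterion. Includes a
    synthetic-recording generator with known ground truth for method
    validation, and orchestration utilities for factorial method comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
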