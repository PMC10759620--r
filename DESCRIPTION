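Package: monovis
Title: Monotreme Color-Vision Analysis: Pigment Spectra, Tuning Sites,
    Selection Tests and Activity Budgets
Version: 0.1.0
Authors@R:
    person("monovis", "maintainers", email = "monovis@example.org",
           role = c("aut", "cre"))
Description: Analytical toolkit for dichromatic (LWS/SWS2) color-vision
    studies in monotremes and other vertebrates. Estimates the wavelength
    of maximum absorbance (lambda-max) of reconstructed visual pigments
    from replicated spectrophotometer scans via smoothing-spline fits of
    dark and difference spectra; predicts LWS lambda-max from opsin coding
    sequences with the additive five-site spectral-tuning rule and reports
    SWS2 key-site differences; tests each branch of a fixed opsin gene
    tree for purifying selection with Nei-Gojobori substitution counting
    and Fisher's exact test after parsimony ancestral reconstruction; and
    analyses 24-h per-minute ethogram data for cathemerality (light/dark
    Wilcoxon tests, day-type chi-squared tests, activity budgets). A
    synthetic-data module simulates Govardovskii-template absorbance
    scans, codon evolution with controlled dN/dS, and two-state circadian
    activity so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    methods,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
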