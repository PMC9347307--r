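Package: rcpskit
Title: Quantitative Autoradiographic Measurement of Regional Cerebral
    Protein Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the quantitative autoradiographic L-[1-14C]leucine
    method for measuring regional rates of cerebral protein synthesis (rCPS).
    Arterial plasma time courses are integrated to form the specific-activity
    input function, film autoradiograms are calibrated against co-exposed
    14C standards and quantified over labelled regions of interest, and the
    operational equation converts terminal tissue 14C concentrations into
    nmol/g/min synthesis rates. Includes genotype group comparisons with
    mixed-design ANOVA and Bonferroni-corrected post hoc tests, a factorial
    ANOVA interface for normalized Western-blot intensity tables, and a
    forward simulator that generates complete synthetic studies (plasma
    draws, phantom autoradiograms, calibration standards) with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
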