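Package: isoturn
Title: Stable Isotope Turnover and Diet-Tissue Discrimination After a Diet Switch
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits growth-based and time-based first-order one-compartment
    incorporation models to delta-13C and delta-15N time series from
    laboratory diet-switch experiments, and derives tissue turnover
    half-lives (G50/D50), near-complete turnover (G95/D95), the partition of
    turnover between growth dilution and metabolic replacement, and
    diet-tissue discrimination factors. Includes lipid normalization of raw
    isotope values, growth-rate estimation from dry weights, a synthetic
    diet-switch experiment generator with known ground truth, and an
    end-to-end analysis pipeline producing a per-diet, per-isotope,
    per-model report. Developed around the early rearing of seahorse
    (Hippocampus reidi) juveniles switched from copepods to Artemia nauplii,
    but applicable to any single-tissue diet-switch design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
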