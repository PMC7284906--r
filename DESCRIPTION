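Package: tsimquant
Title: Targeted SIM-ddMS2 Metabolite Identification and Relative
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Standard-free targeted metabolomics for high-resolution
    LC-MS: computes deprotonated precursor m/z and isotope envelopes from
    molecular formulas, builds targeted single-ion-monitoring (tSIM)
    inclusion lists, extracts ppm-windowed ion chromatograms, integrates
    chromatographic peaks, annotates MS2 fragments by subformula
    enumeration, applies negative-control detection filtering, fits
    calibration curves with LOD/LOQ, and performs reference-normalized
    relative quantification with group statistics. Ships a seeded
    simulator of tSIM-ddMS2 acquisitions so the whole pipeline is
    testable end to end, with a bundled fluoropyrimidine
    (5-fluorouracil metabolite) target panel.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    mzR,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
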