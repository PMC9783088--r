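Package: paperwick
Title: Capillary Wicking Models for Porous Paper Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models capillary imbibition of saliva into porous paper
    membranes (lateral-flow strips) used for point-of-care nucleic acid
    extraction. Provides the Lucas-Washburn closed-form wicking law, a
    one-dimensional two-phase Darcy finite-volume solver with
    Brooks-Corey capillary closure, calibration of permeability from
    manufacturer wicking rates, model-versus-observation comparison of
    wicking traces, and generators for synthetic bench measurements
    (noisy quantized front readings, per-segment analyte concentrations,
    saliva viscosity series). Ships parameter presets for the Whatman
    CF4, MF1 and Fusion 5 membranes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
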