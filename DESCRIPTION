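Package: protofit
Title: Proton-Binding Models for Soluble Bio-Organic Substances from
    Potentiometric Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemical modeling of the acid-base behavior of soluble
    bio-organic substances (SBOs) and humic-like polyelectrolytes from
    potentiometric titration data.  Provides a multi-site protonation
    speciation solver built on the proton mass balance, glass-electrode
    calibration with an acidic junction-potential term, weighted
    nonlinear least-squares refinement of cumulative protonation
    constants and site concentrations in electromotive-force space,
    model comparison by the weighted standard deviation of the fit, and
    the breakdown of total carboxyl and organic nitrogen pools into
    carboxylic, phenolic, amide and non-amide components by combining
    titration results with 13C NMR and elemental-analysis composition
    data.  Includes a synthetic-data generator emulating the titration
    design (instrument-resolution noise on EMF and delivered volume) so
    every pipeline stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
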