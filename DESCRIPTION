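Package: diazoflux
Title: Marine Diazotroph Niche Modelling and N2 Fixation Flux Budgets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative chain from shipboard 15N2-tracer
    incubations and nifH gene quantification to basin-scale nitrogen
    fixation budgets. Computes volumetric and depth-integrated N2 fixation
    rates with detection limits and replicate-propagated uncertainty, fits
    qPCR standard curves and converts Ct values to absolute nifH copy
    concentrations, models per-taxon ecological niches of cyanobacterial
    diazotrophs as generalized additive models of log10 depth-integrated
    nifH abundance against sea-surface temperature, dissolved iron and
    phosphate, projects fitted niches onto gridded monthly climatologies,
    classifies taxon-dominance regions, and converts regional areal rates
    and areas into teragram-per-year nitrogen fluxes. Includes a
    synthetic-data generator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    ncdf4,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
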