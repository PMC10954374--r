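Package: diatomLDG
Title: Biogeography of Stream Diatom Species Richness in Southwestern South
    America
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for biogeographical patterns of stream diatom
    species richness along a temperate latitudinal gradient. Implements
    predictor construction (number of limiting resources, glaciation exposure
    from ice-sheet history tables, detection-limit substitution, latitudinal
    bands), incidence-based rarefaction and extrapolation of band richness, a
    from-scratch Elements of Metacommunity Structure inference (reciprocal
    averaging, coherence, turnover, boundary clumping, fixed-fixed swap null
    model, Presley classification), and a twelve-model additive-model
    comparison suite fitted with penalized regression splines. A
    synthetic-data generator emulates the site, ice-history and community
    structure the analysis assumes, so the whole pipeline is testable without
    field data.
License: MIT
Encoding: UTF-8
Imports:
    mgcv,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
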