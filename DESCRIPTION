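Package: idrphase
Title: Amyloid and Phase-Separation Propensity Prediction for Disordered
    Protein Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Trains, selects and evaluates lightweight logistic-regression
    classifiers of amyloid aggregation and liquid-liquid phase separation
    (LLPS) propensity on mean-pooled sequence embeddings, converts fragment
    probabilities into per-residue propensity profiles by multi-window
    tiling, computes category-level enrichment statistics over a disordered
    proteome (Brunner-Munzel rank tests with Benjamini-Hochberg FDR control
    and a composition-averaged baseline), quantifies local score shifts
    induced by single-residue variants with Fisher tail-enrichment tests and
    bootstrap odds-ratio intervals, and provides composition-preserving
    permutation controls plus seeded synthetic-data generators so that the
    whole pipeline is testable with deterministic toy embedders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
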