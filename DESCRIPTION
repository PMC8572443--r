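Package: gpacc
Title: Reference Population Size and the Accuracy of Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the size of the reference population limits
    the accuracy of genomic estimated breeding values (GEBVs) in livestock
    populations. Provides a forward-in-time genotype simulator calibrated to
    beef-cattle-like linkage disequilibrium, quantitative-trait simulation
    with gamma-distributed QTL effects, marker and animal quality control,
    VanRaden genomic relationship matrices, GBLUP with fixed variance
    components, exact REML for the single-GRM animal model, nested
    reference/test cross-validation, maximum-likelihood estimation of the
    number of independent chromosome segments (Me) from accuracy curves, and
    closed-form accuracy theory (expected GEBV accuracy, LD-based effective
    population size, progeny-test EBV accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
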