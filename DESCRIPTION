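Package: clonefit
Title: Clonal Fitness, Competition and Growth-Rate-Corrected Drug Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of drug-sensitive and drug-resistant tumour
    cell clones grown in mono- and co-culture. Fits logistic population growth
    models to confluence or fluorescence time series to estimate intrinsic
    growth rates, doubling times and time-to-threshold; fits a two-clone
    Lotka-Volterra competition model to co-culture curves with residual
    bootstrap uncertainty on the competition-coefficient ratio; fits
    four-parameter logistic dose-response curves (absolute IC50, fold
    resistance, mixture predictions) and normalized growth-rate inhibition
    (GR) metrics including GR50; normalizes and scores multi-plate 384-well
    viability screens (per-plate fold change to control median, dataset robust
    Z-scores, primary and validation hit calling); and normalizes, reduces and
    tests per-cell morphology feature tables. Ships seeded synthetic-data
    generators with ground-truth sidecars for every input the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
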