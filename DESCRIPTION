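Package: stabrate
Title: Stability-Constrained Arrhenius Models of Amino Acid Substitution Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models empirical amino acid replacement rates as an Arrhenius
    process in which the energy barrier of a substitution is the median
    change in protein folding stability (ddG, kcal/mol) measured across a
    proteome-wide mutational scan. Provides tools to summarize site-level
    ddG scans into a 20 x 20 source-by-destination matrix, build reversible
    instantaneous rate matrices Q = S * Pi from PAML-style exchangeability
    files (DSO78, JTT, LG), partition the 380 ordered substitution pairs
    onto five Arrhenius curves differing in their pre-exponential factor,
    and predict rates that are compared with the empirical matrices. A
    companion machine-learning stage asks how well the assigned
    pre-exponential group of a pair can be recovered from ten features of
    the standard genetic code, with cross-validated multiclass metrics, a
    stratified random-guessing null, and Gini variable importance.
    Synthetic-data generators with the same statistical structure make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    ranger,
    rpart,
    xgboost,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
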