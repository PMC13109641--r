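Package: mrnet
Title: Master Regulators of Yeast Replicative Lifespan from Mutant
    Expression Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers master regulators (MRs) of yeast replicative lifespan
    by fitting a weighted LASSO regression of per-mutant percent lifespan
    change on genome-wide log2 expression fold-changes, with
    reliability weights derived from the number of mother cells assayed
    and two strategies for regularising the singular self-deletion
    entry of each mutant.  Downstream tools characterise MR
    responsiveness across long-lived mutants, connect well-predicted
    peripheral-gene mutants to MRs through ranked per-gene lifespan
    contributions, and score transcription-factor target modules on
    differential-expression profiles with rank-sum z-scores.  A
    synthetic mutant-panel generator with planted coefficients and
    modules makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
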