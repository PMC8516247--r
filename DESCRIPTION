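Package: tokensim
Title: Simulation and Model Fitting for the Tokens Decision-Making Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying perceptual decision making under changing
    evidence with the tokens task, in which fifteen tokens jump one by one
    from a central circle toward two targets and the observer predicts which
    target will hold the final majority. Provides exact success-probability
    computation, generators for the standard trial types (easy, ambiguous,
    bias-for, bias-against, random), leaky working-memory evidence traces,
    fast simulators for the evidence accumulation model (EAM) and the
    urgency gating model (UGM), quantile maximum products estimation (QMPE)
    with differential-evolution search, JZS Bayes factors and the behavioral
    summary statistics used in this literature, and a synthetic-study
    generator for end-to-end pipeline validation and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
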