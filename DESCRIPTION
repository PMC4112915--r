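Package: innercrowd
Title: Replication Statistics for the Inner-Crowd Averaging Effect
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Statistical toolkit for studies of the "crowd within" effect,
    in which the average of two guesses from one person tends to beat either
    guess alone. Implements accuracy scoring of repeated percentage guesses
    by mean squared error, Cohen's d_z effect sizes for paired designs with
    confidence intervals, fixed-effect inverse-variance pooling, exact
    noncentral-t power analysis including the d_33% detectability criterion
    for judging replications, JZS (Cauchy-prior) Bayes factors for one- and
    two-sample t tests, a full confirmatory analysis pipeline with
    pre-registered cleaning rules, and a synthetic cohort generator built on
    the internal-sampling account of repeated guessing so the whole pipeline
    runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
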