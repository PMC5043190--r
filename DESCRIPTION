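Package: memovie
Title: Recognition Memory Analysis for Movie Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying episodic recognition memory for movie
    shots in old/new tasks: percent correct, hit and false-alarm rates and
    d-prime with standard finite-sample corrections, forgetting and
    shot-duration curves, permutation tests with Bonferroni correction,
    within- and between-subject consistency against analytic independence
    nulls, per-content-property performance effects, cross-validated
    multivariate regression of group memorability, a balanced-subsample
    linear support-vector classifier for single-trial memorability with
    per-property ablation and label-shuffle null, and behavior-based
    upper-bound predictors. Includes a synthetic-data generator with a
    known logistic response model so every stage is testable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
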