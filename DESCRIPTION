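Package: citscore
Title: Statistical Scoring and Judgment for the Concealed Information Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical discrimination methods for the Concealed Information
    Test (CIT), a psychophysiological memory-detection technique. Provides the
    pooled-standard-deviation effect size d per autonomic measure with
    direction correction and cross-measure averaging, a randomization test
    with permutation-calibrated multiplied-p integration across measures,
    traditional Lykken block scoring as a comparator, three-way decision rules
    (recognized / inconclusive / unrecognized) for known-solution and
    searching CITs at published threshold presets, a synthetic autonomic
    response cohort simulator, and cohort-level operating characteristics
    (hit, correct-rejection and inconclusive rates, ROC/AUC, binned score
    summaries, and searching-CIT false-positive decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
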