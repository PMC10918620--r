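Package: ssbmc
Title: Standard-Sample Bracketing Deltas with Monte Carlo Uncertainty Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes isotope delta values (per mil) from standard-sample
    bracketing (SSB) measurement runs, propagates per-acquisition standard
    errors of the mean isotope ratios into a standard error for each delta,
    and evaluates two tiers of expanded uncertainty for a set of reference
    samples: the classical reproducibility-based 95% bound and a Monte Carlo
    bound that additionally injects each delta's own propagated standard
    error. Includes normality and zero-mean validation tests, a report
    builder mirroring common metrology summary tables, a synthetic SSB run
    simulator with instrumental drift for validation and coverage
    experiments, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
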