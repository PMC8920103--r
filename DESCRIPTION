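Package: iamdelta
Title: Phospholipophilicity-Excess Descriptors and Blood-Brain-Barrier QSPR
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the phospholipophilicity-excess descriptors
    cDelta/Delta'log kw(IAM) from in-silico immobilized-artificial-membrane
    (IAM) retention and octanol-water lipophilicity, recovers the
    isolipophilic-neutral calibration lines from compound tables, and relates
    the descriptors to blood-brain-barrier passage (log BB) by simple and
    subset ordinary-least-squares regression with a full statistics panel
    (r2, leave-one-out q2, SE, F, p, Amemiya predictive criterion). Includes
    an automatic multiple-linear-regression model search with univariate
    pre-screening, variance-inflation-factor collinearity filtering,
    leave-one-out validation and single-compound exclusion, hydrophilic-
    lipophilic balance calculators, seeded synthetic-data generators for
    every stage, and a packaged 56-compound reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
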