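Package: dcmeval
Title: Economic Evaluation of Vital-Statistics Data Collection Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the economic evaluation of data collection methods
    (DCMs) for vital statistics in settings without complete civil
    registration. Aggregates expert quality scores on data-quality criteria
    into composite quality indices (unweighted mean, expert-weighted mean,
    and benefit-of-the-doubt weighting solved by linear programming),
    combines quality with a quantity-of-data measure into a quality-adjusted
    data index (QADI), ranks methods in cost-effectiveness league tables by
    cost per QADI, and computes data-envelopment-analysis (DEA)
    cost-efficiency scores under constant or variable returns to scale.
    Includes a Monte Carlo simulator of expert scoring panels based on
    triangular distributions, a stylised worked example with two policy
    scenarios, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
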