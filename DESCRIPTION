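Package: nsum
Title: Network Scale-Up Estimation of Hidden Population Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the size of hidden or hard-to-reach
    populations from aggregated relational data using the network scale-up
    method (NSUM). Implements the crude scale-up estimator, visibility
    (transparency) and popularity (barrier-effect) corrections, Monte Carlo
    and bootstrap uncertainty intervals, sensitivity analysis over personal
    network sizes, demographic tabulation of reported alters, and a seeded
    synthetic survey generator for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
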