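Package: anrc
Title: Aquaculture Nutrient Removal Calculator for Farmed Eastern Oysters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes harvest-associated nitrogen removal by farmed eastern
    oysters (Crassostrea virginica) from mean shell height and harvest count,
    and the reverse calculation of the number of oysters required to offset a
    given nitrogen load. Ships a versioned constants registry holding regional
    mean tissue and shell nitrogen concentrations and 50th-quantile allometric
    power regressions of dry weight on shell height, and provides the robust
    statistical machinery needed to re-derive every constant from a
    morphometrics dataset: trimmed means, percentile-bootstrap one-way tests
    for independent groups, Theil-Sen regression on log-transformed data with
    bootstrap comparison of group slopes and intercepts, and nonlinear
    quantile (pinball-loss) power regression. Includes a synthetic oyster
    record generator for end-to-end testing without external data, a
    command-line interface, and a permit-facing report generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
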