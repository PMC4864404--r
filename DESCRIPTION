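Package: landpov
Title: Rural Populations on Degrading Agricultural Land and the
    Growth-Poverty Link
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a two-stage analysis of land degradation and rural
    poverty. Stage one classifies gridded agricultural land as degrading or
    improving from net-primary-productivity trends, overlays market-access
    (travel-time) surfaces to separate remote from accessible land, and
    tabulates rural populations on each class by country and region. Stage
    two builds cross-country poverty spells from household-survey pairs,
    computes annualized log growth rates of headcount poverty and mean
    income, and estimates a two-equation simultaneous system in which the
    spatial distribution of the rural population modifies the
    poverty-reducing effect of income growth (OLS, two-stage least squares,
    seemingly unrelated regressions and three-stage least squares).
    Synthetic landscape and survey-panel generators with known parameters
    make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
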