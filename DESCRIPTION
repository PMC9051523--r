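Package: nfertpolicy
Title: Bio-Economic Simulation of Nitrogen Fertilizer Policy Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how four nitrogen-fertilizer policy instruments (an
    N:maize price-ratio tax, a fee on N leaching, a fee on the N balance
    surplus, and a voluntary rate reduction) change economically optimal N
    rates, nitrate leaching, maize yield, farm profits, government
    collections, policy (deadweight) cost and welfare across a population of
    maize-soybean fields. Includes a seeded generator of field-level N
    response curves (quadratic-plateau yield, convex two-year leaching) with
    early-season covariates; policy-conditional profit optimisation on a
    discrete N-rate grid; a random-forest N-rate recommendation stage
    evaluated leave-one-year-out; lump-sum compensation and welfare
    accounting; and cost-efficiency, demand-elasticity, field-level effect
    and N-balance diagnostic analyses, with ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
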