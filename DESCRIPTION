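Package: otostock
Title: Age-Based Life History and Otolith Shape Analysis for Fish Stock Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for describing the population structure of exploited fish
    from otolith data. Implements marginal increment analysis and ageing
    precision statistics (average percent error, coefficient of variation),
    fractional (biological) age assignment, von Bertalanffy growth model
    fitting with bootstrap confidence intervals and hierarchical
    likelihood-ratio comparison of growth curves among groups, derived
    life-history quantities (growth performance index, lifespan, natural
    mortality, age at maturity), and a multivariate otolith-shape workflow
    (allometric size correction, principal coordinates analysis, PERMANOVA,
    and dispersion analysis). Includes a synthetic population generator that
    emulates site-structured age, growth, maturity and otolith morphometry
    so the whole pipeline can be exercised and tested without raw survey
    data, plus bundled reference age-length keys and growth parameter tables
    for yellowtail snapper (Ocyurus chrysurus) from the southern Gulf of
    Mexico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    ape,
    vegan,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
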