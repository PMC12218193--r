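Package: lenspol
Title: Perceived Ideological Polarization Through Group-Specific Lenses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure perceived ideological polarization in survey
    opinion data. Each identity group views the opinion space through a
    "lens" built from the principal components of its in-group opinion
    covariance, which induces a Mahalanobis-type subjective distance.
    Mean perceived disagreement is a weighted average of pairwise subjective
    distances, and its change between survey waves decomposes exactly into a
    pure (opinion-driven) component and a lens-specific (perception-driven)
    component. Includes survey ingestion with auditable exclusion ledgers,
    a synthetic wave generator for group-structured opinion data, tidy and
    glance methods, ggplot2 autoplot methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
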