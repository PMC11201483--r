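Package: causalhh
Title: Causal Structure Learning for Linear SEMs via Partial-Correlation
    Constraints and a Choice-Function Hyper-Heuristic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-phase causal discovery for continuous data generated by
    linear structural equation models. A constraint phase tests conditional
    independence with Bayes-factor-thresholded partial correlations to build
    restricted search spaces and a v-structure prior; a multi-population
    selection hyper-heuristic with a choice function then searches DAG space
    under a decomposable BIC score fitted by ordinary least squares. Includes
    a linear-SEM simulator with closed-form population covariances, structure
    readers and writers (edge list and BIF), and structural evaluation
    metrics (added/deleted/reversed arcs, directed-edge F1, BIC of learned
    and reference structures).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    generics,
    ggplot2,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
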