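Package: timealloc
Title: Microscopic and Macroscopic Models of Labor-Leisure Time Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Solves an entropy-regularized, average-reward semi-Markov
    decision process in which a subject on a cumulative handling time
    schedule alternates price-long work bouts with freely chosen leisure
    durations.  Provides the closed-form softmax policies over leisure
    durations (truncated exponential and gamma), the self-consistent
    average reward rate, simulation of work/leisure ethograms, and the
    two classical macroscopic accounts the microscopic model subsumes:
    CES labor-supply utility with budget-constrained optimization and
    the generalized-matching "mountain" model.  Also derives, from the
    microscopic model, the macroscopic utility function over rewards and
    cumulative leisure whose budget-constrained optimum reproduces the
    microscopic allocation, with the Lagrange multiplier equal to the
    average reward rate (the shadow-price identity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
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
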