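Package: evorescue
Title: Single-Locus Theory and Simulation of Evolutionary Rescue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic theory and exact forward Monte Carlo simulation of
    evolutionary rescue at a single haploid locus after a sudden environmental
    change. Provides closed-form rescue probabilities from new mutation and
    from the standing genetic variation, the rescue-conditioned expected
    population-size trajectory with the Maynard Smith oversampling correction,
    rebound time, minimum expected size, the mutant/wildtype ratio at rebound,
    recovery time, and waiting-time densities for the origin of a successful
    mutation; plus a vectorized branching-process simulator whose ensembles,
    conditioned on rescue, validate every analytic result.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
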