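Package: fcbindr
Title: Multivalent Immune-Complex Binding to Fc-Gamma Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium modeling of multivalent immune complexes built from
    mixtures of IgG subclasses binding to Fc-gamma receptors, with closed-form
    macroscopic binding quantities and an exhaustive configuration-enumeration
    oracle; Bayesian refinement of IgG-FcR affinities from multivalent binding
    screens (log-normal priors built from documented affinities, MAP
    initialization and MCMC sampling); a survival-style regression linking
    model-predicted receptor multimerization on effector cells to in vivo
    target-cell depletion; descriptive summaries (PCA variance explained,
    ANOVA variance partition, intervalency ratios, Spearman tests); and a
    synthetic-data generator emulating the flow-cytometry screen structure so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
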