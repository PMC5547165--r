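Package: neurogini
Title: Neighborhood Income Inequality and Adolescent Cortical Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how neighborhood income inequality and
    household income relate to age-related cortical thinning in
    adolescents, and how inter-regional thinning profiles relate to
    glucocorticoid (NR3C1) and androgen (AR) receptor gene expression
    across 34 cortical regions. Provides Gini coefficient estimation from
    binned, top-coded census income distributions (interval-censored
    lognormal maximum likelihood and exact midpoint Lorenz methods),
    mean-income residualization and median-split grouping of census
    tracts, income-to-needs computation against low-income cut-off
    tables, family-nested interaction models of cortical thickness,
    per-subgroup slope fits and cluster-robust slope contrasts,
    Fisher z-transformed regional thickness-age correlation profiles
    regressed on receptor expression profiles, Benjamini-Hochberg false
    discovery rate control, and a fully seeded synthetic-cohort
    generator that reproduces the nested study design with known ground
    truth for every stage.
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
    lme4,
    lmtest,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
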