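Package: hbocsim
Title: Family-Structured Microsimulation of Hereditary Breast and Ovarian
    Cancer Genetic Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time, individual-based microsimulation of hereditary
    breast and ovarian cancer (HBOC) in proband-centred family units.
    Generates multi-generational pedigrees from parity distributions, assigns
    monogenic (eight-gene panel) and polygenic cancer risk, simulates breast
    and ovarian cancer natural history with a preclinical sojourn-time model,
    population and high-risk breast screening, risk-reducing surgery, and
    diagnostic plus cascade (predictive) genetic testing with family-knowledge
    propagation. Four genetic-testing scenarios can be compared under common
    random numbers, with tidy outcome tables for detection rates, cancer
    incidence, and life expectancy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    jsonlite,
    ggplot2,
    generics,
    survival,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
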