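Package: synlethnet
Title: Cross-Species Synthetic Lethal Interaction Networks and Flap
    Endonuclease Inhibitor Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring double-knockdown viability screens with a
    multiplicative genetic-interaction model and a three-times-average-SEM
    synthetic-lethality call, assembling bipartite yeast-versus-human
    conservation networks of chromosome-instability genes, and analysing
    fluorescence-quench flap-endonuclease inhibitor screens (initial rates,
    percent inhibition, four-parameter logistic IC50 fits, quencherless-substrate
    counterscreen and rule-of-five triage).  Seeded simulators for plate-based
    siRNA screens, enzyme kinetic traces, and conservation-network fixtures make
    every stage testable without external data.
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
    minpack.lm,
    purrr,
    readr,
    rlang (>= 1.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
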