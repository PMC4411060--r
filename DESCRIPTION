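Package: arenium
Title: Geometric Prediction of Aromatic Hydroxylation Regioselectivity and
    Antioxidant Assay Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which ring position of a monocyclic aromatic substrate a
    diiron monooxygenase will hydroxylate, by docking the cationic arenium
    (sigma-complex) intermediate of each candidate hydroxylation into an
    active-site model with seeded Monte Carlo energy minimization and scoring
    the docked pose against a reference complex with two geometric predictors:
    the displacement of the oxygen-accepting carbon from the reference C4
    position and the deviation of the Fe2-O-Cn-Cm torsion from its reference
    value. Also provides the downstream analytics for characterizing the
    hydroxylated products: DPPH radical-scavenging quantification (percent
    reduction, EC50 by Hill regression, TEC50 plateau time, antiradical
    efficiency) and biotransformation kinetics (formation rates, molar yields,
    product distributions), plus synthetic-data generators with known ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
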