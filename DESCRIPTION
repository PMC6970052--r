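Package: esccea
Title: Cost-Effectiveness of Chemoradiation With or Without Esophagectomy
    in Esophageal Squamous Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-tree plus monthly Markov cohort model comparing
    definitive chemoradiation (CRT) against chemoradiation followed by
    esophagectomy (CRT+S) for locally advanced esophageal squamous cell
    carcinoma. Implements phase-of-care cost attribution (initial,
    continuing, end-of-life), discounted quality-adjusted life years,
    incremental cost-effectiveness ratios and net monetary benefit,
    deterministic sensitivity analysis (tornado, two-way grids, threshold
    search), and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves and frontier. Ships a seeded
    individual-level microsimulation as an independent oracle for the
    cohort algebra, and synthetic fixtures (parametric life table,
    survival-calibrated monthly death rates) for the inputs that are not
    published.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
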