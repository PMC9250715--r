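Package: sofatraj
Title: Organ-Dysfunction Trajectory Subphenotyping for Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to derive and evaluate trajectory-based sepsis
    subphenotypes from intensive-care organ-dysfunction scores. Builds
    72-hour Sequential Organ Failure Assessment (SOFA) trajectories from
    raw time-stamped measurements (6-hour worst-value windows, LOCF/NOCB
    imputation, zero fill), clusters patients with dynamic time warping
    and hierarchical agglomerative clustering into Rapidly/Delayed
    Worsening/Improving archetypes, re-derives the groups with
    group-based trajectory modeling, characterizes them with standard
    two-sample and survival statistics, and predicts membership early
    with a random forest explained by Monte-Carlo permutation Shapley
    values. A seeded synthetic-cohort generator with known latent
    archetypes makes the whole pipeline testable without access to
    restricted clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    survival,
    randomForest,
    data.table,
    jsonlite,
    zoo,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
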