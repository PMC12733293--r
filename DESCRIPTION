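Package: fqcross
Title: Dynamical Network Analysis and Cross-Reactivity Classification for
    Antibody-Hapten Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Trajectory-based dynamical network analysis for antibody-hapten
    complexes and competitive-ELISA cross-reactivity computation. Partitions a
    protein-ligand system into coarse-grained nodes (one per residue, three to
    four per ligand with a designated quinolone-ring node), builds a
    contact-restricted correlation network from coordinate trajectories with
    edge weights -log|C|, computes edge betweenness centrality by Brandes'
    algorithm, and summarises the ligand's integration into the antibody
    network as the quinolone-ring betweenness sum, a threshold descriptor that
    discriminates cross-reactive from non-cross-reactive fluoroquinolone
    haptens. Also fits four-parameter logistic calibration curves for
    competitive ELISA, extracts IC50 values at the inflection point, and
    computes cross-reactivity percentages with censoring. Includes a seeded
    synthetic-data generator (multivariate-Gaussian node displacements with
    tunable ligand-protein coupling, and noisy logistic inhibition panels)
    that provides ground-truthed test inputs in place of molecular-dynamics
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
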