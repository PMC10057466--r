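Package: redoxsar
Title: Structure-Based Modeling of Oxidative Versus Reductive Photocatalytic Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the split between hydroxyl-radical (oxidative) and
    superoxide (reductive) degradation pathways of organic micropollutants
    under TiO2 photocatalysis, and links it to molecular structure. Computes
    the K coefficient (ratio of pathway-specific degradation shares) from
    scavenger kinetics, molecular descriptors (Moran autocorrelations,
    3D-MoRSE, CATS2D pharmacophore pairs, binary 2D atom pairs) from SMILES
    via OpenBabel, and builds genetic-algorithm-selected multiple linear
    regression models with leave-one-out / leave-many-out cross-validation,
    Y-scrambling, external validation and Williams-plot applicability-domain
    diagnostics. Ships a 30-compound reference dataset and synthetic-data
    generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on the PATH)
Config/testthat/edition: 3
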