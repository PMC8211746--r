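Package: pdgain
Title: Expected Phylogenetic Diversity Gains and Losses for Conservation
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies species and areas of interest for conserving
    phylogenetic diversity (PD) under per-species extinction probabilities.
    Implements the expected-PD engine and the derived species scores
    (fair-proportion evolutionary distinctiveness, EDGE, HEDGE, LEDGE),
    cell-level scores on an equal-area reference grid (richness, rarity,
    PD, phylogenetic endemism, and the expected-PD gain/loss scores GexpPD
    and LexpPD), percentile hotspot detection, and protected-area coverage
    overlays, together with seeded generators of synthetic phylogenies,
    Red List statuses, gridded ranges and protection fields for testing
    the full pipeline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
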