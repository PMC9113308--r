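Package: dlcquartet
Title: Quartet Probabilities and Consistency Checks Under the
    Duplication-Loss-Coalescence Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying quartet-based species-tree inference when
    gene families evolve by gene duplication, gene loss and incomplete
    lineage sorting.  Implements the two-stage duplication-loss-coalescence
    (DLCoal) generative model: a birth-death duplication/loss process along
    the branches of a species tree produces a locus tree, and a bounded
    multispecies coalescent on the locus tree produces a gene tree.
    Provides exact Tavare lineage-count probabilities, closed-form quartet
    probabilities for four-leaf locus trees under every duplication
    placement, ASTRAL-one and ASTRAL-multi quartet extraction from
    multi-copy gene trees, exact small-scale species-tree estimation by
    quartet score, and a Monte-Carlo harness that verifies the closed forms
    and the statistical-consistency properties by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    ggplot2,
    phangorn,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
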