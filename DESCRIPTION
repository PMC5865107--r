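Package: pollinet
Title: Pollen Metabarcoding Networks and Pollen-Load Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing pollinator pollen loads characterised by DNA
    metabarcoding of the rbcL plant barcode. Implements consensus taxonomic
    assignment of amplicon reads from tabular alignment hit files (top
    bit-score rule with genus-majority fallback and a curation tier),
    conversion of per-insect read tallies to percentage and presence/absence
    profiles, construction of per-site bipartite pollen-transport networks
    with the specialisation indices H2' (network level) and d' (species
    level) computed from first principles with exact small-matrix entropy
    bounds, and a comparison suite: binary Jaccard distances, permutational
    MANOVA with strata, one-vs-rest contrast batteries under the Dunn-Sidak
    correction, and a tie-corrected Kruskal-Wallis test. A Dirichlet-
    multinomial simulator generates reference databases, site communities,
    individual pollen loads, reads and hit tables with known ground truth so
    the whole pipeline can be exercised and calibrated without sequence
    archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
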