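Package: orfam
Title: Evolutionary and Machine-Learning Analysis of Odorant-Receptor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of large chemoreceptor gene
    families, built around the insect odorant-receptor (OR) family. Starting
    from a master multiple sequence alignment, orthologous cluster
    assignments, a species taxonomy with sociality flags, and published
    protein-by-chemical response panels, the package identifies alignment
    positions predictive of chemical response with cross-validated random
    forests, scores per-cluster conservation of those positions against the
    background conservation of the whole protein, quantifies taxon-specific
    cluster expansions as log2 sequence-to-species enrichments, and compares
    binding-site conservation between cluster groups (for example clusters
    expanded in social versus solitary insects) with rank tests. A seeded
    synthetic-family generator with planted binding positions makes the whole
    pipeline testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    caret,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
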