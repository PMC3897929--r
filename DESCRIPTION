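Package: snapsets
Title: Versioned Cross-Species Gene, Transcript and Protein Set Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species-bound sets of genes, transcripts and proteins kept
    transitively consistent (a member protein forces its transcript into the
    set, a member transcript forces its gene), with level-aware set algebra,
    container/snapshot version trees with a replayable action history,
    parent-child-union hypergeometric GO term enrichment with replicated and
    pruned display trees, protein-interaction neighborhood expansion,
    pathway/EC three-way classification, microRNA/disease/drug association
    lookups, orthology-based translation of sets between species, and
    multi-user group pools with two authorization levels. Reference data
    (genome models, GO ontology and annotations, interactions, orthology,
    associations, pathways) load from documented plain-text formats, and a
    deterministic synthetic-bundle generator makes every module testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
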