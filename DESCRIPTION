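Package: sremine
Title: Mining Co-Occurring Exonic Splicing Regulatory Elements from
    Score-Ranked de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers sets of co-occurring exonic splicing regulatory
    elements (enhancers and silencers) of variable length from hexamer
    enrichment scores and exon sequences.  Builds the k-dimensional de
    Bruijn graph, ranks k-mers by an enrichment score, induces enhancer and
    silencer subgraphs over the top- and bottom-ranked k-mers, and applies
    two levels of graph mining: enumeration of maximal alpha-cohesive
    connected subgraphs (candidate variable-length elements supported by at
    least alpha exons), followed by ordered set-enumeration of collections
    of those subgraphs sharing at least theta exons.  A sequence-level
    filtering stage spells each subgraph, locates the spelled elements in
    the exon windows, merges overlapping same-type occurrences into longer
    elements, and reports the final combinatorial element sets.  Includes a
    synthetic-data generator with planted motifs and a random-sequence
    negative control for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
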