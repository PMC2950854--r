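Package: cmca
Title: Conservation-Mutation Correlation Analysis of Protein Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects co-evolving residue positions in an aligned protein
    family. From an aligned FASTA the package builds the position
    frequency matrix over 20 amino acids plus gap, removes gap-dominated
    columns (fewer than 20 percent natural residues), scores per-symbol
    mutability with a mutative-factor function that peaks at the column's
    average frequency, and computes position conservation and position
    mutation correlation matrices. Strongly correlated position pairs are
    extracted, clustered into contiguous matrix regions, and assembled
    into mutually mutative position networks, with dual reporting in
    alignment and reference-sequence numbering. A seeded synthetic-family
    generator with planted couplings supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
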