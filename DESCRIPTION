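Package: pepgraph
Title: Protein-Graphs for Exhaustive Peptide Search-Space Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Encodes UniProtKB protein entries (canonical sequence, isoforms,
    and annotated sequence features such as variants, conflicts, mutagenesis
    sites and maturation cleavages) as compact labelled directed acyclic
    graphs in which, after in-silico enzymatic digestion, every complete
    path from the start to the end vertex spells one peptide.  Provides
    exact arbitrary-precision dynamic-programming counts of the induced
    peptide search space (total and binned by length, missed cleavages or
    feature usage), a binary compressed-sparse-row graph serialization in
    topological order, bound-pruned traversal to enumerate all peptides
    whose monoisotopic mass falls in a precursor-derived mass window, and
    FASTA exporters for global and precursor-specific search databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
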