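Package: ClonalKit
Title: Single-Cell Immune Receptor Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell V(D)J immune-receptor repertoire analysis
    from 10x Genomics Cell Ranger contig annotations or AIRR Rearrangement
    tables. Pairs T-cell receptor or immunoglobulin chains per cell barcode
    into clonotype calls (by gene usage, CDR3 nucleotide, CDR3 amino acid, or
    the strict gene+nucleotide combination), computes clonal-architecture
    statistics (unique-clonotype quantification, abundance, CDR3 length
    distributions, clonal homeostasis and proportional occupancy), repertoire
    diversity (Shannon, inverse Simpson, Chao1, ACE), pairwise repertoire
    overlap (overlap coefficient, Morisita-Horn), and Jensen-Shannon
    divergence clustering of clone-size distributions. Clonotype calls join
    onto per-cell expression metadata for cluster-level repertoire analysis.
    Includes a seeded synthetic-repertoire generator with planted clonal
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
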