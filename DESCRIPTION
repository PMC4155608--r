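Package: famtrend
Title: Trend Images, Similarity Sorting and Consensus-Mutation Mining for
    Protein Families
Version: 0.1.0
Authors@R:
    person("famtrend", "maintainers", email = "maintainers@famtrend.dev",
           role = c("aut", "cre"))
Description: Non-interactive toolkit for mining protein-family multiple
    sequence alignments. Renders pixel-per-residue family overview rasters
    ("trend images") under physicochemical coloring schemes, ranks family
    members against a reference sequence by seven similarity weights
    (edit distance, class-weighted edit distance, positional and
    compositional residue matches, shared n-grams, fragment frequency,
    edit distance on selected columns), computes per-column residue
    distributions, consensus and conservation statistics, diffs a parent
    against a mutant to locate maximal runs of change, shortlists
    consensus-restoring candidate mutations and terminus-symmetric
    position pairs, and maps candidates onto PDB structure coordinates to
    measure proximity to a designated site. Includes a seeded synthetic
    family generator and a command-line interface so every analysis is
    reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    png,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
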