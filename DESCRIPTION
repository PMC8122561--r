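Package: plastcomp
Title: Comparative Plastome Structure, Junction and Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of annotated chloroplast genomes
    (plastomes): detection of the quadripartite LSC-IRb-SSC-IRa structure from
    raw sequence, per-region length and GC statistics, deduplicated gene
    census, IR/SC junction-gene mapping, extraction of homologous coding and
    noncoding loci across a genome panel, per-locus nucleotide-diversity
    statistics (segregating sites, Eta, haplotype diversity, pi,
    parsimony-informative sites) with hypervariable-region ranking, sliding
    window percent-identity profiles, p-distance/neighbour-joining sanity
    trees, and a seeded synthetic plastome generator that provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
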