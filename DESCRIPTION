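Package: plastocompare
Title: Comparative Analysis of Quadripartite Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of circular quadripartite
    chloroplast genomes. Detects the inverted-repeat (IR) pair and partitions a
    plastome into LSC/IRb/SSC/IRa, locates the four IR junctions and their
    flanking genes, censuses dispersed repeats (forward, palindromic, reverse,
    complement) and microsatellites (SSRs) with MISA-style thresholds, extracts
    homologous coding and non-coding loci across taxa, aligns them and tallies
    variable and parsimony-informative characters to rank mutation hotspots as
    candidate molecular markers. Includes a seeded synthetic plastome generator
    with Jukes-Cantor evolution so every stage is testable against known ground
    truth, and an orchestration layer that writes the standard comparison
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
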