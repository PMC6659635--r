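Package: plastovar
Title: Comparative Plastome Structural Variation, Repeat Dynamics and Event Rates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative analysis of closely related chloroplast genomes
    (plastomes): detection of the quadripartite LSC/IRb/SSC/IRa structure and
    junction-to-gene distances; extraction and outgroup polarization of SNV and
    indel events from a multiple sequence alignment; Fitch parsimony placement
    of events on a time-calibrated phylogeny with per-branch and per-lineage
    occurrence rates in events per million years; exact-match detection of
    tandem, palindromic and dispersed repeats and perfect microsatellites
    (SSRs) at configurable minimum sizes; permutation tests for variant
    enrichment in repeats and their flanks; and a plastome evolution simulator
    (substitutions, length-skewed indels, tandem duplications along a timetree)
    that emits tip genomes, the true alignment and a ground-truth event log so
    every stage can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
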