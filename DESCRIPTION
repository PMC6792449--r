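Package: sortvir
Title: Recovery and Characterization of Giant-Virus Genomes from Sorted-Cell Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for recovering nucleocytoplasmic large DNA
    virus (NCLDV, "giant virus") genomes from flow-sorted cell metagenomes:
    tetranucleotide-frequency/GC contig binning, an ancestral-marker PSSM
    screen with rRNA exclusion, RDP-style bootstrap naive-Bayes rRNA read
    classification, exact-overlap secondary assembly with assembly
    statistics, fragment-based average nucleotide identity, 99
    percent-identity read mapping with SNV pileup, orthogroup
    presence-absence clustering with multiscale (AU) bootstrap support,
    rhodopsin motif typing, and competitive translated read recruitment
    against a decoy database. Includes a synthetic sorted-cell community
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
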