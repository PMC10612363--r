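Package: ystrkit
Title: Forensic and Population-Genetic Analysis of Y-STR Haplotype Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for forensic and population-genetic analysis of Y-chromosomal
    short tandem repeat (Y-STR) haplotype tables: marker panel definitions with
    multi-copy locus and allele-anomaly handling (microvariants, duplications,
    null alleles); haplotype-level forensic parameters (haplotype diversity,
    match probability, discrimination capacity) and per-locus statistics (gene
    diversity, PIC, power of discrimination and exclusion, paternity index);
    pairwise population distances by haploid AMOVA RST on repeat scores and by
    Nei's standard genetic distance; classical multidimensional scaling and
    UPGMA dendrograms with Newick export; median-joining haplotype networks
    with maximum-parsimony post-processing; and a founder-expansion stepwise
    mutation model simulator for generating structured synthetic samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan
Config/testthat/edition: 3
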