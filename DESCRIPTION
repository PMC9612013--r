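Package: plastidkit
Title: Plastid Genome Structure, Isoform Phasing, Variants and Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the quadripartite structure of plastid
    (chloroplast) genomes and the structural heteroplasmy generated by
    flip-flop recombination between the inverted repeats. Detects the
    inverted-repeat pair of a circular plastome and partitions it into
    LSC/IR/SSC/IR regions, classifies long reads spanning an inverted
    repeat into the two co-existing structural isoforms and estimates the
    isoform ratio with a binomial test, classifies multiple-sequence-
    alignment columns into single-nucleotide variants and indel events
    with gap-aware coordinate lift-over and marker-list intersection, and
    builds neighbor-joining phylogenies with bootstrap support, outgroup
    rooting and monophyly tests. Includes a ground-truthed simulator for
    plastomes, isoform mixtures, long reads and populations evolved on a
    known tree, plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    dplyr,
    generics,
    ggplot2,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
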