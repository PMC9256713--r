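Package: tdnaseek
Title: Characterization of Transgene and Cisgene Integration from
    Paired-End Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for molecular characterization of
    transformation events in plant genomes from paired-end whole-genome
    sequencing: discovery of T-DNA integration sites and their flanking
    sequences via chimeric read-pair analysis with homology-blacklist
    filtering, junction contig assembly and arrangement inference,
    copy-number estimation from calibrated sequencing depth and from
    droplet digital PCR replicate counts, and detection of residual
    plasmid backbone sequence. Includes a paired-end read simulator that
    builds ground-truthed transgenic and cisgenic genomes so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
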