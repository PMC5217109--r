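Package: dsbfootprints
Title: Footprint Analysis of Nuclease-Induced Double-Strand Break Repair
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calls CRISPR/Cas9 repair footprints (deletions, insertions,
    delins, substitutions) from Sanger-sequenced amplicon clones by
    end-anchored comparison to a reference amplicon, canonicalizes
    junction ambiguity, annotates microhomology and templated insertions
    (direct, partial and reverse-complement matches with primer identity,
    the polymerase-theta signature), models loss-of-restriction-site
    detectability, and compares deletion and insertion length
    distributions between genotypes with two-tailed Mann-Whitney U tests.
    Includes a calibrated simulator of repair outcomes in wild-type and
    NHEJ-mutant (ku80, parp1 parp2) backgrounds so every pipeline stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
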