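Package: clampdesign
Title: Design and In Silico Validation of PCR Clamps for Host DNA Depletion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing PNA (peptide nucleic acid) and
    C3-spacer blocking-primer PCR clamps that suppress host (plant)
    organellar and nuclear DNA co-amplification in 16S/ITS metabarcoding
    while sparing microbial templates. Builds per-column conservation
    profiles from host plus microbe multiple alignments, enumerates and
    ranks clamp candidates against compositional and thermodynamic design
    criteria, estimates DNA/DNA and PNA/DNA duplex melting temperatures,
    predicts amplicons and clamp blocking outcomes for degenerate primer
    pairs, computes copy-number normalization recipes for mock
    communities, and reports host-versus-microbial read fractions. A
    synthetic-panel generator produces aligned host/microbe fixtures with
    planted clamp sites for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
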