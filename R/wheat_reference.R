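#' Wheat clamping assay oligonucleotide panel
#'
#' The traditional primers, C3-spacer blocking primers, and PNA clamps of
#' the wheat endophyte clamping assays: 16S V5V7 (799F/1193R with four
#' blocking primers and PNA_V5V7), 16S V4 (515F/806R with chloroplast- and
#' mitochondrion-targeting PNAs), and the fungal ITS1/ITS2 assays. All
#' sequences are written 5'->3'.
#'
#' @return Tibble with columns `region`, `name`, `sequence`, `kind`
#'   (`pcr_primer`, `blocking_primer`, `pna`), `orientation` (`forward`/
#'   `reverse` for PCR primers, `NA` otherwise), `three_prime_block`.
#' @export
wheat_clamp_oligos <- function() {
  t <- tibble::tribble(
    ~region, ~name, ~sequence, ~kind, ~orientation,
    "16S_V5V7", "799F", "AACMGGATTAGATACCCKG", "pcr_primer", "forward",
    "16S_V5V7", "1193R", "ACGTCATCCCCACCTTCC", "pcr_primer", "reverse",
    "16S_V5V7", "BL_V5V7_1S", "GGACTGCCAGTGAGATACTGGAG", "blocking_primer", NA,
    "16S_V5V7", "BL_V5V7_2S", "AAAGGTGCGTGCCGCA", "blocking_primer", NA,
    "16S_V5V7", "BL_V5V7_1L", "CTCACGAGGGACTGCCAGTGAGATACTGGAGGAAGG",
    "blocking_primer", NA,
    "16S_V5V7", "BL_V5V7_2L", "CGCTCCGAAACAAAGAAAAAGGTGCGTGCCGCA",
    "blocking_primer", NA,
    "16S_V5V7", "PNA_V5V7", "CCCACGGAGACCTACCT", "pna", NA,
    "16S_V4", "515F", "GTGCCAGCMGCCGCGGTAA", "pcr_primer", "forward",
    "16S_V4", "806R", "GGACTACHVGGGTWTCTAAT", "pcr_primer", "reverse",
    "16S_V4", "PNA_V4chloro", "GCGTCTGTAGGTGGCTTTTC", "pna", NA,
    "16S_V4", "PNA_V4mito", "CGGAATGCTCTCGAAACC", "pna", NA,
    "ITS1", "ITS1", "TCCGTAGGTGAACCTGCGG", "pcr_primer", "forward",
    "ITS1", "58A2R", "CTGCGTTCTTCATCGAT", "pcr_primer", "reverse",
    "ITS1", "18SF", "GTAAAAGTCGTAACAAGGTTTC", "pcr_primer", "forward",
    "ITS1", "ITS2_KYO2", "TTYRCTRCGTTCTTCATC", "pcr_primer", "reverse",
    "ITS1", "PNA_ITS1", "CTATTTAATCCACACGACTCTCGG", "pna", NA,
    "ITS2", "gITS7ngs", "GTGARTCATCRARTYTTTG", "pcr_primer", "forward",
    "ITS2", "ITS4ngsUni", "CCTSCSCTTANTDATATGC", "pcr_primer", "reverse",
    "ITS2", "fITS9", "GAACACAGCGAAATGTGA", "pcr_primer", "forward",
    "ITS2", "ITS4-Fun", "AGCCTCCGCTTATTGATATGCTTAART", "pcr_primer", "reverse",
    "ITS2", "PNA_ITS2", "CGGCATCTGGTCCCTCGTCTC", "pna", NA
  )
  t |> mutate(three_prime_block = .data$kind == "blocking_primer")
}

#' Wheat clamping assay read counts
#'
#' Pre-denoising read counts from the wheat field-sample clamping assays:
#' per blocking condition, plant chloroplast (`host_chloroplast`) and
#' mitochondrial (`host_mitochondrial`) 16S/18S read counts versus
#' bacterial counts, and for the fungal assays plant (`host_nuclear`) vs.
#' fungal counts. These are the inputs of [read_fraction_report()].
#'
#' @return Tidy tibble: `assay`, `primer_set`, `condition`, `component`,
#'   `count`.
#' @export
wheat_clamp_read_counts <- function() {
  v5v7 <- tibble::tribble(
    ~condition, ~host_chloroplast, ~host_mitochondrial, ~microbial,
    "No blocking", 5, 32754, 12163,
    "BL_V5V7_1S", 7, 16830, 51824,
    "BL_V5V7_1L", 5, 29075, 58373,
    "BL_V5V7_2S", 9, 1956, 107240,
    "BL_V5V7_2L", 5, 1988, 96726,
    "PNA_V5V7", 2, 229, 104078
  ) |> mutate(assay = "16S_V5V7", primer_set = "799F/1193R")
  v4 <- tibble::tribble(
    ~condition, ~host_chloroplast, ~host_mitochondrial, ~microbial,
    "No blocking", 58505, 8749, 48,
    "PNA_V4chloro", 28572, 22378, 24567,
    "PNA_V4mito", 68645, 941, 9652,
    "PNA_V4chloro + PNA_V4mito", 7141, 4450, 47404
  ) |> mutate(assay = "16S_V4", primer_set = "515F/806R")
  bact <- bind_rows(v5v7, v4) |>
    tidyr::pivot_longer(
      c("host_chloroplast", "host_mitochondrial", "microbial"),
      names_to = "component", values_to = "count"
    )
  fung <- tibble::tribble(
    ~primer_set, ~condition, ~host_nuclear, ~microbial,
    "18SF/ITS2_KYO2", "No blocking", 34684, 5,
    "18SF/ITS2_KYO2", "PNA_ITS1", 13796, 26269,
    "ITS1/58A2R", "No blocking", 66877, 3623,
    "ITS1/58A2R", "PNA_ITS1", 1738, 32752,
    "gITS7ngs/ITS4ngsUni", "No blocking", 53355, 16,
    "gITS7ngs/ITS4ngsUni", "PNA_ITS2", 6631, 21297,
    "fITS9/ITS4-Fun", "No blocking", 51278, 1769,
    "fITS9/ITS4-Fun", "PNA_ITS2", 4966, 14308
  ) |>
    mutate(assay = ifelse(.data$primer_set %in%
                            c("18SF/ITS2_KYO2", "ITS1/58A2R"),
                          "ITS1", "ITS2")) |>
    tidyr::pivot_longer(c("host_nuclear", "microbial"),
                        names_to = "component", values_to = "count")
  bind_rows(bact, fung) |>
    select("assay", "primer_set", "condition", "component", "count")
}

#' Balanced bacterial mock community member panel (synthetic stand-in)
#'
#' A 17-member bacterial panel mirroring the taxa of the balanced wheat
#' mock community. Genome lengths and 16S copy numbers are typical
#' species-level values and the DNA concentrations are plausible extract
#' yields — the panel is a synthetic stand-in for exercising the
#' copy-number normalization math, not a reproduction of any measured
#' extract table.
#'
#' @return Tibble: `name`, `dna_concentration` (ng/uL), `genome_length`
#'   (bp), `marker_copies_per_genome`.
#' @export
synthetic_mock_members <- function() {
  tibble::tribble(
    ~name, ~dna_concentration, ~genome_length, ~marker_copies_per_genome,
    "Bacillus subtilis", 12.5, 4.2e6, 10,
    "Burkholderia anthina", 8.0, 7.8e6, 6,
    "Enterobacter tabaci", 15.2, 4.6e6, 7,
    "Glutamicibacter creatinolyticus", 5.1, 3.4e6, 5,
    "Methylobacterium bullatum", 3.8, 6.1e6, 5,
    "Microbacterium oxydans", 7.7, 3.9e6, 2,
    "Pantoea agglomerans", 22.4, 4.8e6, 7,
    "Pedobacter foliorum", 2.9, 5.6e6, 2,
    "Pseudomonas cichorii", 18.3, 6.0e6, 5,
    "Pseudomonas fuscovaginae", 9.6, 6.4e6, 5,
    "Pseudomonas lurida", 11.1, 6.2e6, 5,
    "Pseudomonas sivasensis", 6.4, 6.1e6, 5,
    "Pseudomonas syringae", 14.8, 6.1e6, 5,
    "Sphingobacterium thalpophilum", 4.2, 4.9e6, 2,
    "Sphingomonas albertensis", 3.5, 4.3e6, 2,
    "Staphylococcus equorum", 10.9, 2.8e6, 6,
    "Xanthomonas translucens", 13.0, 4.6e6, 2
  )
}
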