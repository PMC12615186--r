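planted_template <- function(left, primer_f, insert, primer_r_site, right) {
  paste0(left, primer_f, insert, primer_r_site, right)
}

test_that("planted primer sites are found with IUPAC semantics", {
  withr::with_seed(17, {
    left <- random_iupac_string(40)
    right <- random_iupac_string(30)
  })
  f515 <- "GTGCCAGCMGCCGCGGTAA"
  concrete <- "GTGCCAGCAGCCGCGGTAA" # M resolved to A
  tpl <- tibble::tibble(id = "t1",
                        residues = planted_template(left, concrete,
                                                    strrep("CT", 50), "", right))
  hits <- find_primer_sites(tpl, tibble::tibble(name = "515F", sequence = f515))
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 41L)
  expect_equal(plus$mismatches, 0L)
})

test_that("3'-terminal mismatches disqualify otherwise tolerable hits", {
  primer <- "ACGTACGTACGT"
  tpl_ok <- tibble::tibble(id = "ok", residues = paste0("TTTT", primer, "TTTT"))
  # same site with the final base changed: 1 mismatch, but in the 3' window
  bad_site <- paste0(substr(primer, 1, 11), "A")
  tpl_bad <- tibble::tibble(id = "bad", residues = paste0("TTTT", bad_site, "TTTT"))
  p <- tibble::tibble(name = "p", sequence = primer)
  expect_equal(nrow(find_primer_sites(tpl_ok, p) |>
                      dplyr::filter(strand == "+")), 1L)
  expect_equal(nrow(find_primer_sites(tpl_bad, p) |>
                      dplyr::filter(strand == "+")), 0L)
  # relaxing the 3' rule readmits it
  expect_equal(nrow(find_primer_sites(tpl_bad, p, three_prime_max = 1L) |>
                      dplyr::filter(strand == "+")), 1L)
})

test_that("primer scanning equals the brute-force all-position oracle", {
  withr::with_seed(19, {
    for (i in 1:20) {
      tpl <- random_iupac_string(300)
      primer <- random_iupac_string(sample(8:15, 1), degenerate = TRUE)
      got <- find_primer_sites(tibble::tibble(id = "t", residues = tpl),
                               tibble::tibble(name = "p", sequence = primer),
                               max_mismatch = 3L)
      want <- oracle_primer_scan(tpl, primer, max_mismatch = 3L)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        got_o <- got[order(got$strand, got$start), ]
        want_o <- want[order(want$strand, want$start), ]
        expect_equal(got_o$start, want_o$start)
        expect_equal(got_o$mismatches, want_o$mismatches)
        expect_equal(got_o$three_prime_mismatch, want_o$three_prime_mismatch)
      }
    }
  })
})

test_that("amplicon lengths follow the planted fixture arithmetic", {
  primers <- v5v7_primers()
  fwd <- primers[primers$orientation == "forward", ]
  rev <- primers[primers$orientation == "reverse", ]
  fwd_c <- expand_degenerate(fwd$sequence)[1] # 19 nt
  rev_site <- expand_degenerate(reverse_complement(rev$sequence))[1] # 18 nt
  withr::with_seed(23, insert <- random_iupac_string(376))
  tpl <- tibble::tibble(
    id = "microbe_like",
    residues = planted_template("GGGG", fwd_c, insert, rev_site, "AAAA")
  )
  amp <- predict_amplicons(tpl, fwd, rev)
  expect_equal(amp$product_length, 376L + 19L + 18L) # 413

  # a 325 bp host-specific insertion grows the product by exactly 325
  withr::with_seed(24, ins325 <- random_iupac_string(325))
  tpl_host <- tibble::tibble(
    id = "host_like",
    residues = planted_template("GGGG", fwd_c,
                                paste0(substr(insert, 1, 200), ins325,
                                       substr(insert, 201, 376)),
                                rev_site, "AAAA")
  )
  amp_host <- predict_amplicons(tpl_host, fwd, rev)
  expect_equal(amp_host$product_length, amp$product_length + 325L)

  # reverse site upstream of the forward site: no product
  tpl_rev <- tibble::tibble(
    id = "inverted",
    residues = planted_template("GGGG", rev_site, insert, fwd_c, "AAAA")
  )
  expect_equal(nrow(predict_amplicons(tpl_rev, fwd, rev)), 0L)

  # self-consistency: the product carries both primer-matching ends
  expect_equal(substr(amp$product_seq, 1, 19), fwd_c)
  expect_equal(substr(amp$product_seq, amp$product_length - 17,
                      amp$product_length), rev_site)
})

test_that("clamp blocking follows the zero-mismatch default", {
  amp <- tibble::tibble(
    template_id = "t", fwd_start = 1L, fwd_end = 10L, rev_start = 51L,
    rev_end = 60L, product_start = 1L, product_end = 60L,
    product_length = 60L,
    product_seq = paste0(strrep("A", 20), "CCTAGGTTCACCTAC", strrep("A", 25))
  )
  exact <- tibble::tibble(name = "exact", sequence = "CCTAGGTTCACCTAC")
  off1 <- tibble::tibble(name = "off1", sequence = "CCTAGGTTCACCTAA")
  expect_equal(predict_clamp_effect(amp, exact)$predicted_outcome, "blocked")
  expect_equal(predict_clamp_effect(amp, off1)$predicted_outcome, "amplifiable")
  expect_equal(predict_clamp_effect(amp, off1,
                                    block_max_mismatch = 1L)$predicted_outcome,
               "blocked")
  # reverse-complement presentation blocks equally
  rc <- tibble::tibble(name = "rc",
                       sequence = reverse_complement("CCTAGGTTCACCTAC"))
  expect_equal(predict_clamp_effect(amp, rc)$predicted_outcome, "blocked")
})

test_that("a >=5-mismatch clamp leaves every microbe amplifiable", {
  p <- simulate_panel(fixture_spec(seed = 5, locus_length = 250,
                                   insertion_length = 40,
                                   insertion_position = 200,
                                   site_min_mismatches = 5))
  primers <- v5v7_primers()
  fwd <- primers[primers$orientation == "forward", ]
  rev <- primers[primers$orientation == "reverse", ]
  ungapped <- p$records |>
    dplyr::mutate(residues = gsub("-", "", residues, fixed = TRUE))
  amp <- predict_amplicons(ungapped, fwd, rev)
  clamp <- tibble::tibble(name = "planted", sequence = p$truth$site_seq)
  eff <- predict_clamp_effect(amp, clamp)
  host_rows <- startsWith(eff$template_id, "host")
  expect_true(all(eff$predicted_outcome[host_rows] == "blocked"))
  expect_true(all(eff$predicted_outcome[!host_rows] == "amplifiable"))
})

test_that("composition bookkeeping is a weighted tally over amplifiable templates", {
  p <- simulate_panel(fixture_spec(seed = 4, locus_length = 220,
                                   insertion_length = 0))
  primers <- v5v7_primers()
  fwd <- primers[primers$orientation == "forward", ]
  rev <- primers[primers$orientation == "reverse", ]
  ungapped <- p$records |>
    dplyr::mutate(residues = gsub("-", "", residues, fixed = TRUE))
  clamp <- tibble::tibble(name = "planted", sequence = p$truth$site_seq)

  # equal weights, clamp blocks only hosts -> microbe fraction 1
  w1 <- ungapped |> dplyr::mutate(weight = 1)
  comp <- predict_composition(w1, fwd, rev, clamps = clamp)
  expect_equal(comp$composition$role, "microbe")
  expect_equal(comp$composition$fraction, 1)

  # no clamps, both roles amplifiable: fractions follow the weights
  w2 <- ungapped |>
    dplyr::mutate(weight = ifelse(role == "host", 2, 1))
  comp2 <- predict_composition(w2, fwd, rev)
  n_host <- sum(w2$role == "host"); n_mic <- sum(w2$role == "microbe")
  hand <- c(host = 2 * n_host, microbe = n_mic)
  hand <- hand / sum(hand)
  got <- setNames(comp2$composition$fraction, comp2$composition$role)
  expect_equal(got[names(hand)], hand, tolerance = 1e-12)
  expect_equal(sum(comp2$composition$fraction), 1, tolerance = 1e-9)

  # blocking monotonicity: adding a clamp never adds amplifiable templates
  amp_before <- comp2$per_template$outcome == "amplifiable"
  amp_after <- predict_composition(w2, fwd, rev,
                                   clamps = clamp)$per_template$outcome ==
    "amplifiable"
  expect_true(all(amp_after <= amp_before))

  # all templates blocked -> defined empty result with warning
  host_only <- w1 |> dplyr::filter(role == "host")
  expect_warning(
    empty <- predict_composition(host_only, fwd, rev, clamps = clamp),
    "empty"
  )
  expect_equal(nrow(empty$composition), 0L)
})
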