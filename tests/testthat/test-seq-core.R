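test_that("FASTA parsing assigns roles, canonicalizes, and validates", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a|host some wheat locus", "acgu", ">b|microbe", "ACGT",
               ">c", "NNRY"), tmp)
  rec <- read_fasta(tmp)
  expect_equal(rec$id, c("a", "b", "c"))
  expect_equal(rec$role, c("host", "microbe", "unknown"))
  expect_equal(rec$residues[1], "ACGT") # lowercase + U both canonicalized
  expect_equal(rec$description[1], "some wheat locus")

  writeLines(c(">a|host", "ACGT", ">a|microbe", "ACGT"), tmp)
  expect_error(read_fasta(tmp), "duplicate")

  writeLines(c(">a|host", "ACXT"), tmp)
  expect_error(read_fasta(tmp), "position 3")
})

test_that("a role map TSV overrides header tags", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a|host", "ACGT", ">b", "TTTT"), fa)
  rec <- read_fasta(fa, role_map = tibble::tibble(id = "b", role = "microbe"))
  expect_equal(rec$role, c("host", "microbe"))
})

test_that("write-then-read round-trips any record collection", {
  withr::with_seed(7, {
    rec <- tibble::tibble(
      id = sprintf("s%d", 1:6),
      description = c("", "desc here", "", "", "x", ""),
      residues = replicate(6, random_iupac_string(sample(10:40, 1),
                                                  degenerate = TRUE)),
      role = sample(c("host", "microbe", "unknown"), 6, replace = TRUE)
    )
  })
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, tmp, width = 17L)
  expect_equal(read_fasta(tmp), rec)
})

test_that("iupac_match reflects base-set intersection and is symmetric", {
  expect_true(iupac_match("M", "A"))
  expect_false(iupac_match("A", "G"))
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  expect_true(all(iupac_match("N", codes)))
  for (a in codes) for (b in codes) {
    expect_equal(iupac_match(a, b), oracle_base_match(a, b))
    expect_equal(iupac_match(a, b), iupac_match(b, a))
  }
  expect_error(iupac_match("-", "A"), "IUPAC")
})

test_that("reverse_complement extends to IUPAC codes and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("M"), "K")
  r806 <- "GGACTACHVGGGTWTCTAAT"
  expect_equal(reverse_complement(reverse_complement(r806)), r806)
  withr::with_seed(11, {
    for (i in 1:50) {
      s <- random_iupac_string(sample(1:30, 1), degenerate = TRUE)
      expect_equal(reverse_complement(reverse_complement(s)), s)
      expect_equal(reverse_complement(s), oracle_revcomp(s))
    }
  })
  expect_error(reverse_complement("AC-T"), "illegal")
})

test_that("purine metrics match the printed clamp panel arithmetic", {
  expect_equal(purine_fraction("CCCACGGAGACCTACCT"), 7 / 17)
  expect_equal(purine_fraction("CCCC"), 0)
  expect_equal(purine_fraction("CGGAATGCTCTCGAAACC"), 0.5)
  expect_equal(max_purine_run("TTTT"), 0L)
  expect_equal(max_purine_run("CGGCATCTGGTCCCTCGTCTC"), 2L)
  expect_equal(max_purine_run("CCCACGGAGACCTACCT"), 5L)
  expect_error(purine_fraction("ACGR"), "degenerate")
  expect_error(max_purine_run(""), "empty")
})

test_that("purine and pyrimidine fractions are complementary", {
  withr::with_seed(3, {
    for (i in 1:20) {
      s <- random_iupac_string(sample(5:30, 1))
      pyr <- purine_fraction(chartr("ACGT", "TGCA", s)) # complement strand
      expect_equal(purine_fraction(s) + pyr, 1)
    }
  })
})

test_that("self-complementary stretch detection matches brute force", {
  expect_equal(self_complementary_stretch("GAATTC", k = 4),
               list(length = 6L, flagged = TRUE))
  expect_equal(self_complementary_stretch("AAAAAA", k = 4),
               list(length = 0L, flagged = FALSE))
  withr::with_seed(5, {
    for (i in 1:40) {
      s <- random_iupac_string(sample(4:30, 1))
      got <- self_complementary_stretch(s, k = 4)
      want <- oracle_self_comp(s, k = 4)
      expect_equal(got$length, want$length, info = s)
      expect_equal(got$flagged, want$flagged, info = s)
    }
  })
  expect_error(self_complementary_stretch(""), "empty")
})

test_that("degenerate expansion enumerates the full variant set", {
  expect_setequal(expand_degenerate("AM"), c("AA", "AC"))
  v <- expand_degenerate("AACMGGATTAGATACCCKG")
  expect_length(v, 4L)
  expect_true(all(!grepl("[^ACGT]", v)))
  expect_error(expand_degenerate("NNNNNNNN", max_variants = 100), "cap")
})
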