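test_that("the guideline screen reproduces the printed clamp panel audit", {
  pnas <- wheat_clamp_oligos() |> dplyr::filter(kind == "pna")
  screen <- screen_clamp_guidelines(pnas |> dplyr::select(name, sequence))
  expect_true(all(screen$purine_fraction <= 0.5))
  v <- function(n) screen$violations[[which(screen$name == n)]]
  expect_true("length" %in% v("PNA_ITS1"))      # 24 nt, over the 21 cap
  expect_true("purine_run" %in% v("PNA_V5V7"))  # GGAGA, run of 5
  expect_true("purine_fraction" %in% v("PNA_V4mito")) # exactly 50%
  expect_equal(screen$length[screen$name == "PNA_ITS1"], 24L)
  expect_equal(screen$max_purine_run[screen$name == "PNA_V5V7"], 5L)
})

test_that("hard mode returns nothing when no column is strictly conserved", {
  withr::with_seed(21, {
    n_col <- 80
    base <- sample(c("A", "C", "G", "T"), n_col, replace = TRUE)
    flip <- function(ch) {
      # every column differs somewhere across the three hosts
      vapply(ch, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    }
    rec <- tibble::tibble(
      id = c("h1", "h2", "m1"),
      residues = c(paste(base, collapse = ""), paste(flip(base), collapse = ""),
                   paste(base, collapse = "")),
      role = c("host", "host", "microbe")
    )
  })
  prof <- build_profile(rec)
  cands <- enumerate_pna_candidates(
    prof, v5v7_primers(),
    design_constraints(constraint_mode = "hard"))
  expect_equal(nrow(cands), 0L)
})

test_that("candidate enumeration equals brute force on a toy alignment", {
  toy <- toy_alignment(n_col = 60, block_start = 16, block_end = 47, seed = 3)
  prof <- build_profile(toy)
  cons <- design_constraints(min_len = 12, max_len = 21)
  cands <- enumerate_pna_candidates(prof, v5v7_primers(), cons)

  # brute force: every (start, length, strand) window whose columns are all
  # host-conserved and gap-free, recomputed from the raw rows
  mat <- do.call(rbind, strsplit(toy$residues, ""))
  hosts <- mat[toy$role == "host", , drop = FALSE]
  conserved <- vapply(seq_len(ncol(mat)), function(j) {
    length(unique(hosts[, j])) == 1L && all(hosts[, j] != "-")
  }, logical(1))
  want <- list()
  for (len in 12:21) {
    for (s in seq_len(ncol(mat) - len + 1L)) {
      if (all(conserved[s:(s + len - 1L)])) {
        want[[length(want) + 1L]] <- c(s, len)
      }
    }
  }
  got <- unique(cands[, c("start", "length")])
  expect_equal(nrow(got), length(want))
  expect_setequal(paste(got$start, got$length),
                  vapply(want, function(w) paste(w[1], w[2]), ""))
  # both strands present for every window
  expect_true(all(table(cands$start, cands$length) %in% c(0L, 2L)))
  # planted-window sub-windows all come from inside the conserved block
  expect_true(all(cands$start >= 16 & cands$end <= 47))
})

test_that("windows with degenerate host consensus are skipped with a note", {
  rec <- tibble::tibble(
    id = c("h1", "m1"),
    residues = c(paste0(strrep("A", 10), "R", strrep("C", 10)),
                 strrep("T", 21)),
    role = c("host", "microbe")
  )
  prof <- build_profile(rec)
  expect_message(
    cands <- enumerate_pna_candidates(prof, v5v7_primers(),
                                      design_constraints(min_len = 12)),
    "degenerate"
  )
  # windows crossing the R column are absent
  expect_true(all(cands$end < 11 | cands$start > 11))
})

test_that("mismatch scoring counts disjoint bases and gaps, per microbe", {
  toy <- toy_alignment(n_col = 60, block_start = 21, block_end = 45,
                       n_mm = 5, seed = 8)
  prof <- build_profile(toy)
  cands <- enumerate_pna_candidates(prof, v5v7_primers())
  scored <- score_candidates(cands, toy)
  microbes <- toy[toy$role == "microbe", ]
  for (i in seq_len(nrow(scored))) {
    per <- scored$per_microbe_mismatches[[i]]
    for (m in seq_len(nrow(microbes))) {
      expect_equal(
        per[[microbes$id[m]]],
        oracle_site_mismatches(scored$site_seq[i], microbes$residues[m],
                               scored$start[i], scored$end[i])
      )
    }
    expect_equal(scored$min_microbe_mismatches[i], min(unlist(per)))
  }
})

test_that("a clamp matching a microbe scores zero; an all-gap site scores length", {
  rec <- tibble::tibble(
    id = c("h1", "m_same", "m_gap"),
    residues = c(strrep("ACGT", 5), strrep("ACGT", 5), strrep("-", 20)),
    role = c("host", "microbe", "microbe")
  )
  prof <- build_profile(rec)
  cands <- enumerate_pna_candidates(prof, v5v7_primers(),
                                    design_constraints(min_len = 12,
                                                       max_len = 12))
  scored <- score_candidates(cands, rec)
  expect_true(all(vapply(scored$per_microbe_mismatches,
                         function(p) p[["m_same"]], integer(1)) == 0L))
  expect_true(all(vapply(scored$per_microbe_mismatches,
                         function(p) p[["m_gap"]], integer(1)) == 12L))
})

test_that("adding a microbe can only lower or preserve the mismatch floor", {
  toy <- toy_alignment(n_col = 70, block_start = 21, block_end = 50, seed = 13)
  prof <- build_profile(toy)
  cands <- enumerate_pna_candidates(prof, v5v7_primers())
  before <- score_candidates(cands, toy)
  extra <- toy[toy$role == "microbe", ][1, ]
  extra$id <- "m_extra"
  extra$residues <- toy$residues[toy$role == "host"][1] # identical to host
  after <- score_candidates(cands, dplyr::bind_rows(toy, extra))
  expect_true(all(after$min_microbe_mismatches <=
                    before$min_microbe_mismatches))
})

test_that("ranking follows the documented key tuple", {
  toy <- toy_alignment(seed = 4)
  prof <- build_profile(toy)
  thermo <- thermo_config()
  scored <- score_candidates(
    enumerate_pna_candidates(prof, v5v7_primers(), thermo = thermo), toy)
  ranked <- rank_candidates(scored, thermo)
  # oracle sort of the same frame by the documented key
  key_ord <- order(-scored$min_microbe_mismatches,
                   abs(scored$tm_pna - thermo$pna_target_tm),
                   scored$n_violations,
                   scored$start,
                   scored$strand != "host")
  expect_equal(ranked$sequence, scored$sequence[key_ord])
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  # pairwise spot rules
  expect_true(all(diff(ranked$min_microbe_mismatches) <= 0))
})

test_that("tie-breaks prefer the Tm closest to the PNA target", {
  cands <- tibble::tibble(
    sequence = c("a", "b"), site_seq = c("a", "b"),
    start = c(5L, 1L), end = c(20L, 16L), length = 16L,
    strand = "host", tm_pna = c(79, 70), purine_fraction = 0.4,
    max_purine_run = 2L, self_comp_len = 0L,
    violations = list(character(), character()), n_violations = 0L,
    per_microbe_mismatches = list(c(m = 6L), c(m = 6L)),
    min_microbe_mismatches = 6L, mean_microbe_mismatches = 6
  )
  ranked <- rank_candidates(cands, thermo_config())
  expect_equal(ranked$sequence, c("a", "b")) # 79 is closer to 80 than 70
})

test_that("blocking-primer designs respect placement geometry", {
  p <- simulate_panel(fixture_spec(seed = 2, locus_length = 300,
                                   insertion_length = 0,
                                   host_divergence = 0.01))
  prof <- build_profile(p$records)
  primers <- v5v7_primers()

  ea_s <- design_blocking_primers(prof, primers, "elongation_arrest", "short")
  expect_equal(nrow(ea_s), 1L)
  expect_true(ea_s$three_prime_block)
  # strictly between the primer binding intervals
  expect_gt(ea_s$start, p$truth$fwd_cols[2])
  expect_lt(ea_s$end, p$truth$rev_cols[1])

  ea_l <- design_blocking_primers(prof, primers, "elongation_arrest", "long")
  expect_gte(ea_l$target_tm, ea_s$target_tm + 9)
  # long design extends the short design at the same locus
  expect_true(grepl(ea_s$sequence, ea_l$sequence, fixed = TRUE) ||
                (ea_l$start <= ea_s$start && ea_l$end >= ea_s$end))

  comp <- design_blocking_primers(prof, primers, "competitive", "short")
  expect_equal(nrow(comp), 1L)
  expect_true(comp$overlapped_primer %in% primers$name)
})

test_that("an impossible geometry yields an explicit no-design result", {
  # hosts vary everywhere between the primers: nothing conserved inside
  withr::with_seed(31, {
    primers <- v5v7_primers()
    fwd <- expand_degenerate(primers$sequence[primers$orientation == "forward"])[1]
    rc_rev <- expand_degenerate(
      reverse_complement(primers$sequence[primers$orientation == "reverse"]))[1]
    mid1 <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    mid2 <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    rec <- tibble::tibble(
      id = c("h1", "h2", "m1"),
      residues = c(paste0(fwd, mid1, rc_rev), paste0(fwd, mid2, rc_rev),
                   paste0(fwd, mid1, rc_rev)),
      role = c("host", "host", "microbe")
    )
  })
  prof <- build_profile(rec)
  res <- design_blocking_primers(prof, v5v7_primers(), "elongation_arrest",
                                 "short")
  expect_equal(nrow(res), 0L)
  expect_match(attr(res, "reason"), "conserved")
})

test_that("tidy and glance summarize candidate tables", {
  toy <- toy_alignment(seed = 6)
  prof <- build_profile(toy)
  ranked <- rank_candidates(
    score_candidates(enumerate_pna_candidates(prof, v5v7_primers()), toy))
  td <- tidy(ranked)
  expect_true(all(c("rank", "sequence", "min_microbe_mismatches") %in% names(td)))
  gl <- glance(ranked)
  expect_equal(gl$n_candidates, nrow(ranked))
  expect_equal(gl$best_min_mismatches, max(ranked$min_microbe_mismatches))
  expect_s3_class(autoplot(ranked), "ggplot")
})
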