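#' Specification for a synthetic host/microbe alignment panel
#'
#' Describes the synthetic study system the generator emulates: a host
#' organellar locus carrying a long insertion absent from microbial
#' homologs (the wheat mitochondrial 18S region has a ~320 bp insertion
#' that several clamps exploit), a family of microbial sequences with
#' controlled per-site divergence, an embedded PCR primer pair, and one
#' planted clamp site that is perfectly conserved across hosts and at
#' least `site_min_mismatches` divergent from every microbe.
#'
#' @param seed Integer seed; the same spec always yields byte-identical
#'   output.
#' @param host_n,microbe_n Number of host / microbial sequences.
#' @param locus_length Ungapped microbial locus length, bp.
#' @param insertion_length Host-specific insertion length, bp (0 disables).
#' @param insertion_position Ancestral position before which the insertion
#'   is placed; default midway between the planted site and the reverse
#'   primer site.
#' @param site_position Ancestral start of the planted clamp site; default
#'   centered between the primer sites.
#' @param site_length Planted site length, nt.
#' @param site_min_mismatches Minimum mismatches every microbe carries
#'   against the planted site.
#' @param microbe_divergence Per-site substitution probability applied to
#'   microbial rows outside protected regions.
#' @param host_divergence Per-site substitution probability applied to
#'   host rows outside the planted site and primer sites.
#' @param primers Primer tibble (`name`, `sequence`, `orientation`);
#'   default the 799F/1193R 16S V5V7 pair.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, host_n = 5L, microbe_n = 8L,
                         locus_length = 500L, insertion_length = 320L,
                         insertion_position = NULL, site_position = NULL,
                         site_length = 17L, site_min_mismatches = 5L,
                         microbe_divergence = 0.10, host_divergence = 0.02,
                         primers = NULL) {
  if (is.null(primers)) {
    primers <- wheat_clamp_oligos() |>
      filter(.data$name %in% c("799F", "1193R")) |>
      select("name", "sequence", "orientation")
  }
  stopifnot(host_n >= 1L, microbe_n >= 1L, locus_length >= 40L,
            insertion_length >= 0L, site_length >= 6L,
            site_min_mismatches >= 0L, site_min_mismatches <= site_length,
            microbe_divergence >= 0, microbe_divergence <= 1,
            host_divergence >= 0, host_divergence <= 1)
  fwd_len <- nchar(primers$sequence[primers$orientation == "forward"][1])
  rev_len <- nchar(primers$sequence[primers$orientation == "reverse"][1])
  interior_lo <- fwd_len + 1L
  interior_hi <- locus_length - rev_len
  if (is.null(site_position)) {
    site_position <- interior_lo +
      max(0L, (interior_hi - interior_lo + 1L - site_length) %/% 2L)
  }
  site_end <- site_position + site_length - 1L
  if (site_position < interior_lo || site_end > interior_hi) {
    abort("planted site does not fit between the primer sites")
  }
  if (is.null(insertion_position)) {
    insertion_position <- min(site_end + 2L +
                                (interior_hi - site_end) %/% 2L,
                              interior_hi)
  }
  if (insertion_length > 0L &&
      insertion_position > site_position && insertion_position <= site_end) {
    abort("insertion must not fall inside the planted site")
  }
  structure(
    list(seed = as.integer(seed), host_n = as.integer(host_n),
         microbe_n = as.integer(microbe_n),
         locus_length = as.integer(locus_length),
         insertion_length = as.integer(insertion_length),
         insertion_position = as.integer(insertion_position),
         site_position = as.integer(site_position),
         site_length = as.integer(site_length),
         site_min_mismatches = as.integer(site_min_mismatches),
         microbe_divergence = microbe_divergence,
         host_divergence = host_divergence,
         primers = primers),
    class = "fixture_spec"
  )
}

random_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob)
}

mutate_chars <- function(ch, rate, protect) {
  if (rate <= 0) return(ch)
  hit <- stats::runif(length(ch)) < rate
  hit[protect] <- FALSE
  idx <- which(hit)
  for (i in idx) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  ch
}

# Rejection-sample a compositionally compliant clamp site (purine content
# < 50%, no purine run > 4, no self-complementary 4-stretch).
compliant_site_seq <- function(len, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    ch <- random_dna(len, prob = c(0.20, 0.30, 0.20, 0.30))
    s <- paste(ch, collapse = "")
    if (purine_fraction(s) < 0.5 && max_purine_run(s) <= 4L &&
        !self_complementary_stretch(s, k = 4L)$flagged) {
      return(ch)
    }
  }
  abort("could not sample a guideline-compliant planted site")
}

#' Generate a synthetic aligned host/microbe panel with ground truth
#'
#' Emits an already-columnized alignment (microbial rows carry gaps across
#' the host insertion, so no aligner is needed downstream) in which the
#' planted clamp site is 100% host-conserved, every microbe differs from
#' it by at least the requested mismatch count, and the primer pair is
#' embedded exactly once per template. The fixture is its own oracle: all
#' ground-truth claims can be re-verified by the profiling, scoring, and
#' in-silico PCR functions.
#'
#' @param spec A [fixture_spec()].
#' @return List with `records` (aligned sequence tibble with roles) and
#'   `truth` (list: `site_start`/`site_end` alignment columns, `site_seq`,
#'   `insertion_start`/`insertion_end` columns or `NA`,
#'   `fwd_primer`/`rev_primer` concrete embedded sequences,
#'   `fwd_cols`/`rev_cols` alignment column intervals,
#'   `site_min_mismatches`).
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, simulate_panel_impl(spec))
}

simulate_panel_impl <- function(spec, tries = 20L) {
  for (attempt in seq_len(tries)) {
    panel <- try(simulate_panel_once(spec), silent = TRUE)
    if (!inherits(panel, "try-error")) return(panel)
  }
  abort(sprintf("failed to generate a valid panel after %d attempts: %s",
                tries, attr(panel, "condition")$message))
}

simulate_panel_once <- function(spec) {
  fwd <- spec$primers |> filter(.data$orientation == "forward")
  rev <- spec$primers |> filter(.data$orientation == "reverse")
  fwd_seq <- sample(expand_degenerate(fwd$sequence[1]), 1L)
  rev_site <- sample(expand_degenerate(reverse_complement(rev$sequence[1])), 1L)
  fwd_len <- nchar(fwd_seq); rev_len <- nchar(rev_site)
  L <- spec$locus_length

  anc <- random_dna(L)
  fwd_pos <- 1L
  rev_pos <- L - rev_len + 1L
  anc[fwd_pos:(fwd_pos + fwd_len - 1L)] <- seq_chars(fwd_seq)
  anc[rev_pos:L] <- seq_chars(rev_site)
  site_idx <- spec$site_position:(spec$site_position + spec$site_length - 1L)
  anc[site_idx] <- compliant_site_seq(spec$site_length)
  protect <- c(fwd_pos:(fwd_pos + fwd_len - 1L), rev_pos:L, site_idx)

  ins_len <- spec$insertion_length
  ins_pos <- spec$insertion_position
  ins_chars <- if (ins_len > 0L) random_dna(ins_len) else character()
  anc2col <- function(p) ifelse(p < ins_pos, p, p + ins_len)
  n_col <- L + ins_len
  ins_cols <- if (ins_len > 0L) ins_pos:(ins_pos + ins_len - 1L) else integer()

  rows <- list()
  for (h in seq_len(spec$host_n)) {
    ch <- mutate_chars(anc, spec$host_divergence, protect)
    full <- character(n_col)
    full[anc2col(seq_len(L))] <- ch
    if (ins_len > 0L) full[ins_cols] <- ins_chars
    rows[[length(rows) + 1L]] <- tibble(
      id = sprintf("host_%02d", h), description = "synthetic host locus",
      residues = paste(full, collapse = ""), role = "host")
  }
  host_site <- anc[site_idx]
  for (m in seq_len(spec$microbe_n)) {
    ch <- mutate_chars(anc, spec$microbe_divergence, protect)
    # force the planted divergence at the clamp site
    mut_at <- sample(seq_along(site_idx), spec$site_min_mismatches)
    for (k in mut_at) {
      ch[site_idx[k]] <- sample(setdiff(c("A", "C", "G", "T"),
                                        host_site[k]), 1L)
    }
    # residual site positions may also diverge
    extra <- setdiff(seq_along(site_idx), mut_at)
    for (k in extra) {
      if (stats::runif(1) < spec$microbe_divergence) {
        ch[site_idx[k]] <- sample(setdiff(c("A", "C", "G", "T"),
                                          host_site[k]), 1L)
      }
    }
    full <- rep("-", n_col)
    full[anc2col(seq_len(L))] <- ch
    rows[[length(rows) + 1L]] <- tibble(
      id = sprintf("microbe_%02d", m),
      description = "synthetic microbial locus",
      residues = paste(full, collapse = ""), role = "microbe")
  }
  records <- bind_rows(rows)

  # each template must carry each primer site exactly once
  ungapped <- records |> mutate(residues = gsub("-", "", .data$residues,
                                                fixed = TRUE))
  fh <- find_primer_sites(ungapped, fwd)
  rh <- find_primer_sites(ungapped, rev)
  ok <- all(table(factor(fh$template_id[fh$strand == "+"],
                         levels = records$id)) == 1L) &&
    all(table(factor(rh$template_id[rh$strand == "-"],
                     levels = records$id)) == 1L)
  if (!ok) abort("spurious or missing primer site; resampling")

  truth <- list(
    site_start = anc2col(spec$site_position),
    site_end = anc2col(spec$site_position + spec$site_length - 1L),
    site_seq = paste(host_site, collapse = ""),
    insertion_start = if (ins_len > 0L) ins_cols[1] else NA_integer_,
    insertion_end = if (ins_len > 0L) ins_cols[ins_len] else NA_integer_,
    fwd_primer = fwd_seq, rev_primer = rev$sequence[1],
    fwd_cols = c(anc2col(fwd_pos), anc2col(fwd_pos + fwd_len - 1L)),
    rev_cols = c(anc2col(rev_pos), anc2col(L)),
    site_min_mismatches = spec$site_min_mismatches
  )
  list(records = records, truth = truth)
}

#' Simulate a labeled read-count table
#'
#' Multinomial draw of host vs. per-taxon microbial read counts at a given
#' host read fraction — the synthetic analogue of a pre-denoising
#' host/microbe count table.
#'
#' @param host_fraction Expected fraction of host reads, in `[0, 1]`.
#' @param total_reads Total reads to distribute (> 0).
#' @param taxa Optional tibble with `taxon` and `fraction` (fractions of
#'   the microbial share, summing to 1); default one pooled `"microbial"`
#'   component.
#' @param seed Integer seed.
#' @param condition Condition label for the output table.
#' @return Tibble `condition`, `component`, `count` suitable for
#'   [read_fraction_report()].
#' @export
simulate_labeled_counts <- function(host_fraction, total_reads,
                                    taxa = NULL, seed = 1L,
                                    condition = "simulated") {
  stopifnot(host_fraction >= 0, host_fraction <= 1)
  if (total_reads <= 0) abort("total_reads must be positive")
  if (is.null(taxa)) {
    taxa <- tibble(taxon = "microbial", fraction = 1)
  }
  stopifnot(abs(sum(taxa$fraction) - 1) < 1e-9)
  probs <- c(host_fraction, (1 - host_fraction) * taxa$fraction)
  comp <- c("host_mitochondrial",
            ifelse(taxa$taxon == "microbial", "microbial",
                   paste0("taxon:", taxa$taxon)))
  counts <- withr::with_seed(seed,
                             as.integer(stats::rmultinom(1L, total_reads, probs)))
  tibble(condition = condition, component = comp, count = counts)
}
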