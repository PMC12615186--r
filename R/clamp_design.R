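#' Design constraints for PNA clamp candidates
#'
#' Encodes the published PNA design guidelines: length between 12 and 21
#' bases, purine content below 50% with no purine run longer than four,
#' no self-complementary stretches, a Tm above both the PCR primers and
#' the extension temperature, and at least five mismatches (SNPs) against
#' every microbial reference so microbial amplification is spared.
#'
#' Published, experimentally validated clamps occasionally breach single
#' guidelines (a 24-nt ITS clamp; a five-purine run; a clamp at exactly 50%
#' purines), so the default `constraint_mode = "soft"` annotates breaches
#' instead of rejecting candidates; `"hard"` enforces every criterion.
#'
#' @param min_len,max_len Candidate length bounds, nt.
#' @param max_purine_fraction Purine content must stay strictly below this.
#' @param max_purine_run Longest tolerated purine run, nt.
#' @param self_comp_k Minimum self-complementary stretch length flagged.
#' @param min_tm_margin_over_primers Required PNA Tm excess over the
#'   hottest PCR primer, degrees C (exclusive bound).
#' @param require_tm_above_extension Must the PNA Tm clear the extension
#'   temperature?
#' @param min_microbe_mismatches Minimum mismatches to every microbial
#'   reference.
#' @param min_conservation Host conservation threshold defining candidate
#'   blocks ("strictly conserved" = 1).
#' @param constraint_mode `"soft"` (annotate breaches) or `"hard"` (filter).
#' @param mismatch_aggregate How per-microbe mismatch counts are collapsed
#'   for ranking: `"min"` (default; matches the at-least-5-SNPs reading) or
#'   `"mean"`.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(min_len = 12L, max_len = 21L,
                               max_purine_fraction = 0.5,
                               max_purine_run = 4L,
                               self_comp_k = 4L,
                               min_tm_margin_over_primers = 0,
                               require_tm_above_extension = TRUE,
                               min_microbe_mismatches = 5L,
                               min_conservation = 1,
                               constraint_mode = c("soft", "hard"),
                               mismatch_aggregate = c("min", "mean")) {
  constraint_mode <- match.arg(constraint_mode)
  mismatch_aggregate <- match.arg(mismatch_aggregate)
  stopifnot(min_len <= max_len, min_len >= 6L,
            max_purine_fraction > 0, max_purine_run >= 1L,
            self_comp_k >= 3L, min_microbe_mismatches >= 0L,
            min_conservation > 0, min_conservation <= 1)
  structure(
    list(min_len = as.integer(min_len), max_len = as.integer(max_len),
         max_purine_fraction = max_purine_fraction,
         max_purine_run = as.integer(max_purine_run),
         self_comp_k = as.integer(self_comp_k),
         min_tm_margin_over_primers = min_tm_margin_over_primers,
         require_tm_above_extension = require_tm_above_extension,
         min_microbe_mismatches = as.integer(min_microbe_mismatches),
         min_conservation = min_conservation,
         constraint_mode = constraint_mode,
         mismatch_aggregate = mismatch_aggregate),
    class = "design_constraints"
  )
}

# Compositional/thermodynamic metrics + named guideline breaches for one
# oligomer. primer_max_tm = NA skips the primer-comparison criterion.
oligo_guideline_check <- function(seq, constraints, thermo, primer_max_tm = NA) {
  n <- nchar(seq)
  pf <- purine_fraction(seq)
  pr <- max_purine_run(seq)
  sc <- self_complementary_stretch(seq, k = constraints$self_comp_k)
  tm <- if (n >= 6L && n <= 30L) tm_pna(seq, thermo) else NA_real_
  v <- character()
  if (n < constraints$min_len || n > constraints$max_len) {
    v <- c(v, "length")
  }
  if (pf >= constraints$max_purine_fraction) v <- c(v, "purine_fraction")
  if (pr > constraints$max_purine_run) v <- c(v, "purine_run")
  if (sc$flagged) v <- c(v, "self_complementary")
  if (!is.na(primer_max_tm) && !is.na(tm) &&
      tm <= primer_max_tm + constraints$min_tm_margin_over_primers) {
    v <- c(v, "tm_vs_primers")
  }
  if (constraints$require_tm_above_extension && !is.na(tm) &&
      tm <= thermo$extension_temperature) {
    v <- c(v, "tm_vs_extension")
  }
  list(length = n, purine_fraction = pf, max_purine_run = pr,
       self_comp_len = sc$length, tm_pna = tm, violations = v)
}

#' Screen oligomers against the PNA design guidelines
#'
#' Computes all compositional and thermodynamic design metrics for a panel
#' of oligomers and lists which guidelines each one breaches. Useful both
#' for auditing published clamps and for re-checking candidates produced by
#' [enumerate_pna_candidates()].
#'
#' @param oligos Tibble with columns `name` and `sequence`.
#' @param constraints A [design_constraints()].
#' @param thermo A [thermo_config()].
#' @param primer_max_tm Tm of the hottest PCR primer in the assay, degrees
#'   C, or `NA` to skip that criterion.
#' @return The input with columns `length`, `purine_fraction`,
#'   `max_purine_run`, `self_comp_len`, `tm_pna`, a list-column
#'   `violations`, and `n_violations`.
#' @examples
#' screen_clamp_guidelines(
#'   tibble::tibble(name = "PNA_V5V7", sequence = "CCCACGGAGACCTACCT")
#' )
#' @export
screen_clamp_guidelines <- function(oligos,
                                    constraints = design_constraints(),
                                    thermo = thermo_config(),
                                    primer_max_tm = NA) {
  stopifnot(all(c("name", "sequence") %in% names(oligos)))
  checks <- map(oligos$sequence, oligo_guideline_check,
                constraints = constraints, thermo = thermo,
                primer_max_tm = primer_max_tm)
  oligos |>
    mutate(
      length = map_int(checks, "length"),
      purine_fraction = map_dbl(checks, "purine_fraction"),
      max_purine_run = map_int(checks, "max_purine_run"),
      self_comp_len = map_int(checks, "self_comp_len"),
      tm_pna = map_dbl(checks, "tm_pna"),
      violations = map(checks, "violations"),
      n_violations = lengths(.data$violations)
    )
}

primer_max_tm <- function(primers, thermo) {
  stopifnot(all(c("name", "sequence") %in% names(primers)))
  max(map_dbl(primers$sequence, tm_dna_nn, config = thermo))
}

#' Enumerate PNA clamp candidates over host-conserved blocks
#'
#' Slides windows of every allowed length over the host-conserved, gap-free
#' blocks of a conservation profile and annotates each window, on both
#' strands, with the full set of design metrics. Windows whose host
#' consensus contains a degenerate base are skipped (a PNA is synthesized
#' as one concrete sequence). In `"hard"` mode only fully compliant
#' candidates are returned; in `"soft"` mode every window is returned with
#' its breaches listed.
#'
#' @param profile A [build_profile()] result.
#' @param primers Tibble of the PCR primer pair: columns `name`,
#'   `sequence`, `orientation` (`"forward"`/`"reverse"`).
#' @param constraints A [design_constraints()].
#' @param thermo A [thermo_config()].
#' @return A `clamp_candidates` tibble: one row per (window, strand) with
#'   columns `sequence` (oligomer as synthesized 5'->3'), `site_seq` (the
#'   host-strand site), `start`/`end` (1-based inclusive alignment
#'   columns), `strand` (`"host"` or `"revcomp"`), the guideline metrics of
#'   [screen_clamp_guidelines()], and empty mismatch fields to be filled by
#'   [score_candidates()].
#' @export
enumerate_pna_candidates <- function(profile, primers,
                                     constraints = design_constraints(),
                                     thermo = thermo_config()) {
  blocks <- host_conserved_blocks(profile,
                                  min_conservation = constraints$min_conservation,
                                  min_len = constraints$min_len)
  p_tm <- primer_max_tm(primers, thermo)
  rows <- list()
  n_skipped <- 0L
  for (b in seq_len(nrow(blocks))) {
    bs <- blocks$start[b]; be <- blocks$end[b]
    for (len in seq(constraints$min_len, min(constraints$max_len, be - bs + 1L))) {
      for (s in seq(bs, be - len + 1L)) {
        cols <- s:(s + len - 1L)
        site <- paste(profile$host_consensus[cols], collapse = "")
        if (grepl("[^ACGT]", site)) { n_skipped <- n_skipped + 1L; next }
        for (strand in c("host", "revcomp")) {
          oligo <- if (strand == "host") site else rc_fast(site)
          chk <- oligo_guideline_check(oligo, constraints, thermo,
                                       primer_max_tm = p_tm)
          rows[[length(rows) + 1L]] <- list(
            sequence = oligo, site_seq = site,
            start = s, end = s + len - 1L, length = len, strand = strand,
            chk = chk
          )
        }
      }
    }
  }
  out <- tibble(
    sequence = map_chr(rows, "sequence"),
    site_seq = map_chr(rows, "site_seq"),
    start = map_int(rows, "start"),
    end = map_int(rows, "end"),
    length = map_int(rows, "length"),
    strand = map_chr(rows, "strand"),
    tm_pna = map_dbl(rows, ~ .x$chk$tm_pna),
    purine_fraction = map_dbl(rows, ~ .x$chk$purine_fraction),
    max_purine_run = map_int(rows, ~ .x$chk$max_purine_run),
    self_comp_len = map_int(rows, ~ .x$chk$self_comp_len),
    violations = map(rows, ~ .x$chk$violations)
  )
  out$n_violations <- lengths(out$violations)
  if (n_skipped > 0L) {
    rlang::inform(sprintf(
      "%d window(s) skipped: degenerate host consensus inside the window",
      n_skipped))
  }
  if (constraints$constraint_mode == "hard") {
    out <- out |> filter(.data$n_violations == 0L)
  }
  attr(out, "primer_max_tm") <- p_tm
  class(out) <- c("clamp_candidates", class(out))
  out
}

#' Score clamp candidates against aligned microbial sequences
#'
#' Counts, for every candidate and every microbial record, the alignment
#' positions where the clamp site and the microbial residue cannot pair: a
#' position mismatches when the IUPAC base sets are disjoint, and a
#' microbial gap at a clamp column counts as a mismatch (a clamp spanning a
#' host-specific insertion cannot bind the microbe at all). Degenerate
#' microbial bases that overlap the clamp base count as matches — this
#' understates divergence, never overstates clamp safety.
#'
#' @param candidates A [enumerate_pna_candidates()] result.
#' @param records The aligned sequence tibble the profile was built from
#'   (its `microbe` rows are used); must share the profile's column space.
#' @return `candidates` with list-column `per_microbe_mismatches` (named
#'   integer vectors), plus `min_microbe_mismatches` and
#'   `mean_microbe_mismatches`.
#' @export
score_candidates <- function(candidates, records) {
  microbes <- records |> filter(.data$role == "microbe")
  if (nrow(microbes) == 0L) abort("no microbe records to score against")
  n_col <- unique(nchar(microbes$residues))
  if (length(n_col) != 1L) abort("microbe records have unequal lengths")
  if (nrow(candidates) && max(candidates$end) > n_col) {
    abort("candidate columns exceed the microbial alignment width")
  }
  mat <- alignment_matrix(microbes)
  per <- map(seq_len(nrow(candidates)), function(i) {
    cols <- candidates$start[i]:candidates$end[i]
    site <- seq_chars(candidates$site_seq[i])
    counts <- map_int(seq_len(nrow(mat)), function(m) {
      res <- mat[m, cols]
      gap <- res == "-"
      mm <- gap
      if (any(!gap)) {
        mm[!gap] <- !iupac_match(site[!gap], res[!gap])
      }
      sum(mm)
    })
    stats::setNames(counts, microbes$id)
  })
  candidates |>
    mutate(
      per_microbe_mismatches = per,
      min_microbe_mismatches = map_int(per, ~ as.integer(min(.x))),
      mean_microbe_mismatches = map_dbl(per, mean)
    )
}

#' Rank scored clamp candidates
#'
#' Orders candidates by the design objective: most mismatches to the
#' closest (or average) microbial sequence first, then PNA Tm closest to
#' the design target, then fewest guideline breaches, then leftmost start
#' with the host-strand oligomer before its reverse complement. The key
#' tuple is a total order, so the ranking is deterministic.
#'
#' @param candidates A [score_candidates()] result.
#' @param thermo A [thermo_config()] (supplies the PNA target Tm).
#' @param aggregate `"min"` or `"mean"` mismatch aggregation (defaults to
#'   the mode recorded nowhere else: pass the one from your constraints).
#' @return The candidates sorted, with a `rank` column prepended.
#' @export
rank_candidates <- function(candidates, thermo = thermo_config(),
                            aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!"min_microbe_mismatches" %in% names(candidates)) {
    abort("candidates must be scored with score_candidates() first")
  }
  key <- if (aggregate == "min") candidates$min_microbe_mismatches
         else candidates$mean_microbe_mismatches
  out <- candidates |>
    mutate(.agg = key,
           .tm_dist = abs(.data$tm_pna - thermo$pna_target_tm),
           .strand_ord = ifelse(.data$strand == "host", 0L, 1L)) |>
    arrange(desc(.data$.agg), .data$.tm_dist, .data$n_violations,
            .data$start, .data$.strand_ord) |>
    mutate(rank = row_number()) |>
    select(-".agg", -".tm_dist", -".strand_ord") |>
    select("rank", dplyr::everything())
  class(out) <- c("clamp_candidates", class(out))
  out
}

#' Design a C3-spacer blocking primer from a conservation profile
#'
#' Blocking primers are ordinary oligonucleotides with a 3' C3 spacer that
#' prevents extension. Two placements are supported: `"competitive"`
#' designs overlap one PCR primer's binding site and out-compete it on
#' host templates; `"elongation_arrest"` designs bind a host-conserved
#' region strictly between the two primer sites and stall the polymerase.
#' The `"short"` class targets a Tm a few degrees above the PCR primers
#' (default +5), the `"long"` class a larger excess (default +15); the
#' seed oligomer is extended base-by-base along the host consensus until
#' the target Tm is met or conserved sequence runs out, so a long design
#' at a locus is an extension of the short design at that locus.
#'
#' @param profile A [build_profile()] result.
#' @param primers Primer tibble (`name`, `sequence`, `orientation`).
#' @param strategy `"competitive"` or `"elongation_arrest"`.
#' @param length_class `"short"` or `"long"`.
#' @param thermo A [thermo_config()].
#' @param short_delta,long_delta Tm target excess over the hottest primer,
#'   degrees C.
#' @param min_conservation Host conservation required of the columns used.
#' @param overlap_primer For `"competitive"`: name of the primer to
#'   overlap; default picks the primer whose site abuts the most conserved
#'   host sequence.
#' @return A `blocking_design` tibble with columns `name`, `sequence`
#'   (5'->3', the 3' end carries the C3 spacer), `kind`,
#'   `three_prime_block`, `strategy`, `length_class`, `overlapped_primer`,
#'   `tm_estimate`, `target_tm`, `start`, `end` (alignment columns of the
#'   binding site). When no geometrically valid conserved region exists
#'   the tibble has zero rows and carries the failure reason in
#'   `attr(, "reason")`.
#' @export
design_blocking_primers <- function(profile, primers,
                                    strategy = c("elongation_arrest",
                                                 "competitive"),
                                    length_class = c("short", "long"),
                                    thermo = thermo_config(),
                                    short_delta = 5, long_delta = 15,
                                    min_conservation = 1,
                                    overlap_primer = NULL) {
  strategy <- match.arg(strategy)
  length_class <- match.arg(length_class)
  delta <- if (length_class == "short") short_delta else long_delta
  p_tm <- primer_max_tm(primers, thermo)
  target <- p_tm + delta

  cons <- consensus_sequence(profile, degap = TRUE)
  hits <- locate_primer_pair(cons$sequence, primers)
  if (is.null(hits)) {
    return(blocking_failure("primer pair not found on the host consensus"))
  }
  # usable columns: host-conserved, gap-free, concrete consensus
  usable <- profile$host_conservation >= min_conservation &
    profile$host_gap_fraction == 0 &
    profile$host_consensus %in% c("A", "C", "G", "T")

  if (strategy == "competitive") {
    cand_primers <- if (is.null(overlap_primer)) primers$name else overlap_primer
    for (pn in cand_primers) {
      h <- hits[hits$name == pn, ]
      seed_cols <- cons$columns[h$start:h$end]
      grown <- grow_oligo(profile, usable, seed_cols, target, thermo,
                          orientation = h$orientation)
      if (!is.null(grown)) {
        return(blocking_result(grown, strategy, length_class,
                               overlapped_primer = pn, target))
      }
    }
    return(blocking_failure(
      "no conserved host sequence adjacent to a primer site"))
  }

  # elongation arrest: conserved block strictly between the primer sites
  fwd <- hits[hits$orientation == "forward", ]
  rev <- hits[hits$orientation == "reverse", ]
  inner_lo <- max(cons$columns[fwd$end]) + 1L
  inner_hi <- min(cons$columns[rev$start]) - 1L
  blocks <- host_conserved_blocks(profile, min_conservation,
                                  min_len = 12L) |>
    filter(.data$start >= inner_lo, .data$end <= inner_hi)
  # restrict to concrete-consensus sub-runs
  if (nrow(blocks) == 0L) {
    return(blocking_failure(
      "no host-conserved block between the primer binding sites"))
  }
  blocks <- blocks |> arrange(desc(.data$length))
  for (b in seq_len(nrow(blocks))) {
    cols_all <- blocks$start[b]:blocks$end[b]
    cols_all <- cols_all[usable[cols_all]]
    if (length(cols_all) < 12L) next
    mid <- cols_all[ceiling(length(cols_all) / 2)]
    seed_cols <- cols_all[abs(cols_all - mid) <= 5L]
    if (length(seed_cols) < 12L) seed_cols <- cols_all[seq_len(12L)]
    grown <- grow_oligo(profile, usable, seed_cols, target, thermo,
                        orientation = "forward")
    if (!is.null(grown)) {
      return(blocking_result(grown, strategy, length_class,
                             overlapped_primer = NA_character_, target))
    }
  }
  blocking_failure("no usable concrete conserved run between the primers")
}

# Locate one hit per primer on the degapped host consensus; NULL when any
# primer is absent.
locate_primer_pair <- function(consensus, primers) {
  res <- list()
  for (i in seq_len(nrow(primers))) {
    ori <- primers$orientation[i]
    query <- if (ori == "forward") primers$sequence[i]
             else reverse_complement(primers$sequence[i])
    hit <- best_ungapped_hit(consensus, query, max_mismatch = 2L)
    if (is.null(hit)) return(NULL)
    res[[i]] <- tibble(name = primers$name[i], orientation = ori,
                       start = hit$start, end = hit$end)
  }
  bind_rows(res)
}

# Extend seed columns stepwise along usable columns until target Tm.
grow_oligo <- function(profile, usable, seed_cols, target, thermo,
                       orientation) {
  cols <- sort(seed_cols)
  if (any(diff(cols) != 1L)) return(NULL)
  n_total <- nrow(profile)
  site <- function(cl) paste(profile$host_consensus[cl], collapse = "")
  oligo_of <- function(cl) {
    s <- site(cl)
    if (grepl("[^ACGT]", s)) return(NULL)
    if (orientation == "forward") s else reverse_complement(s)
  }
  cur <- oligo_of(cols)
  if (is.null(cur)) return(NULL)
  tm_of <- function(o) if (nchar(o) >= 8L) tm_dna_nn(o, thermo) else -Inf
  tm <- tm_of(cur)
  repeat {
    if (tm >= target) break
    # extend at the oligo 5' end first, falling back to the 3' side
    ext_left <- cols[1] - 1L
    ext_right <- cols[length(cols)] + 1L
    grew <- FALSE
    order_sides <- if (orientation == "forward") c("left", "right")
                   else c("right", "left")
    for (side in order_sides) {
      nxt <- if (side == "left") ext_left else ext_right
      if (nxt >= 1L && nxt <= n_total && usable[nxt]) {
        cand_cols <- if (side == "left") c(nxt, cols) else c(cols, nxt)
        o <- oligo_of(cand_cols)
        if (!is.null(o)) {
          cols <- cand_cols; cur <- o; tm <- tm_of(o); grew <- TRUE; break
        }
      }
    }
    if (!grew) break
  }
  if (nchar(cur) < 12L || !is.finite(tm)) return(NULL)
  list(sequence = cur, start = cols[1], end = cols[length(cols)], tm = tm)
}

blocking_result <- function(grown, strategy, length_class,
                            overlapped_primer, target) {
  out <- tibble(
    name = sprintf("BL_%s_%s", toupper(substr(strategy, 1, 4)),
                   toupper(substr(length_class, 1, 1))),
    sequence = grown$sequence,
    kind = "blocking_primer",
    three_prime_block = TRUE,
    strategy = strategy,
    length_class = length_class,
    overlapped_primer = overlapped_primer,
    tm_estimate = grown$tm,
    target_tm = target,
    start = grown$start,
    end = grown$end
  )
  class(out) <- c("blocking_design", class(out))
  out
}

blocking_failure <- function(reason) {
  out <- tibble(
    name = character(), sequence = character(), kind = character(),
    three_prime_block = logical(), strategy = character(),
    length_class = character(), overlapped_primer = character(),
    tm_estimate = double(), target_tm = double(),
    start = integer(), end = integer()
  )
  attr(out, "reason") <- reason
  class(out) <- c("blocking_design", class(out))
  out
}

#' @method tidy clamp_candidates
#' @export
tidy.clamp_candidates <- function(x, ...) {
  x |>
    as_tibble() |>
    select(dplyr::any_of(c("rank", "sequence", "start", "end", "length",
                           "strand", "tm_pna", "purine_fraction",
                           "max_purine_run", "self_comp_len",
                           "min_microbe_mismatches",
                           "mean_microbe_mismatches", "n_violations")))
}

#' @method glance clamp_candidates
#' @export
glance.clamp_candidates <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    n_compliant = sum(x$n_violations == 0L),
    best_min_mismatches = if (!is.null(x$min_microbe_mismatches) &&
                              nrow(x)) max(x$min_microbe_mismatches)
                          else NA_integer_,
    best_tm_pna = if (nrow(x)) x$tm_pna[which.max(
      if (!is.null(x$min_microbe_mismatches)) x$min_microbe_mismatches
      else rep(0, nrow(x)))] else NA_real_
  )
}

#' Plot candidate mismatch divergence along the alignment
#'
#' @param object A scored `clamp_candidates` tibble.
#' @param ... Unused.
#' @return A ggplot of candidate start vs. minimum microbial mismatches,
#'   colored by guideline compliance.
#' @method autoplot clamp_candidates
#' @export
autoplot.clamp_candidates <- function(object, ...) {
  stopifnot("min_microbe_mismatches" %in% names(object))
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$start, .data$min_microbe_mismatches,
                 colour = .data$n_violations == 0L)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "alignment column (candidate start)",
                  y = "min mismatches to any microbe",
                  colour = "guideline-compliant") +
    ggplot2::theme_minimal()
}
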