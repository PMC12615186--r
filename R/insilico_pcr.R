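# Mismatch counts of `query` (IUPAC, length m) at every ungapped offset of
# `template` (IUPAC, length n >= m). Returns integer vector over the
# n - m + 1 start positions.
offset_mismatch_counts <- function(template_chars, query_chars) {
  n <- length(template_chars); m <- length(query_chars)
  if (m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  mm <- integer(length(starts))
  for (j in seq_len(m)) {
    mm <- mm + !IUPAC_MATCH_MATRIX[cbind(query_chars[j],
                                         template_chars[starts + j - 1L])]
  }
  mm
}

# Single best (fewest-mismatch, leftmost) hit of query on template, or NULL
# if the best exceeds max_mismatch.
best_ungapped_hit <- function(template, query, max_mismatch = 2L) {
  tch <- seq_chars(canonicalize_seq(template))
  qch <- seq_chars(canonicalize_seq(query))
  mm <- offset_mismatch_counts(tch, qch)
  if (!length(mm) || min(mm) > max_mismatch) return(NULL)
  s <- which.min(mm)
  list(start = s, end = s + length(qch) - 1L, mismatches = mm[s])
}

#' Find primer binding sites on a template
#'
#' Scans both strands of each template with an IUPAC-aware position-by-
#' position comparison. A site is reported when the total mismatch count is
#' within `max_mismatch` and no more than `three_prime_max` mismatches fall
#' in the primer's 3'-terminal window — 3' mismatches are what abort
#' polymerase extension, which is exactly why some primer pairs avoid host
#' organellar templates on their own.
#'
#' @param templates Tibble with columns `id` and `residues` (ungapped).
#' @param primer Tibble row (or one-row tibble) with `name` and `sequence`.
#' @param max_mismatch Maximum total mismatches per hit.
#' @param three_prime_window Length of the 3'-terminal window, nt.
#' @param three_prime_max Maximum mismatches tolerated in that window.
#' @return Tibble: `template_id`, `primer`, `strand` (`"+"` = primer
#'   sequence read on the template strand, `"-"` = on its reverse
#'   complement), `start`, `end` (1-based inclusive template interval),
#'   `mismatches`, `three_prime_mismatch`.
#' @export
find_primer_sites <- function(templates, primer,
                              max_mismatch = 2L,
                              three_prime_window = 5L,
                              three_prime_max = 0L) {
  stopifnot(all(c("id", "residues") %in% names(templates)),
            all(c("name", "sequence") %in% names(primer)))
  pseq <- canonicalize_seq(primer$sequence[1])
  pch <- seq_chars(pseq)
  m <- length(pch)
  w <- min(three_prime_window, m)
  out <- list()
  for (i in seq_len(nrow(templates))) {
    tch <- seq_chars(canonicalize_seq(templates$residues[i],
                                      what = templates$id[i]))
    for (strand in c("+", "-")) {
      qch <- if (strand == "+") pch else seq_chars(reverse_complement(pseq))
      mm <- offset_mismatch_counts(tch, qch)
      if (!length(mm)) next
      # per-start mismatches inside the primer's 3'-terminal window
      tp_idx <- if (strand == "+") seq(m - w + 1L, m) else seq_len(w)
      tp <- integer(length(mm))
      starts <- seq_along(mm)
      for (j in tp_idx) {
        tp <- tp + !IUPAC_MATCH_MATRIX[cbind(qch[j], tch[starts + j - 1L])]
      }
      keep <- which(mm <= max_mismatch & tp <= three_prime_max)
      if (length(keep)) {
        out[[length(out) + 1L]] <- tibble(
          template_id = templates$id[i], primer = primer$name[1],
          strand = strand, start = keep, end = keep + m - 1L,
          mismatches = mm[keep], three_prime_mismatch = tp[keep] > 0L
        )
      }
    }
  }
  if (length(out)) bind_rows(out) else tibble(
    template_id = character(), primer = character(), strand = character(),
    start = integer(), end = integer(), mismatches = integer(),
    three_prime_mismatch = logical()
  )
}

#' Predict PCR amplicons for a primer pair on a set of templates
#'
#' Pairs every plus-strand forward-primer hit with every downstream
#' minus-strand reverse-primer hit within the product-length cap. The
#' product spans from the forward primer's 5' end to the reverse primer's
#' 5' end inclusive, so `product_length` includes both primers. All
#' pairings are reported; no shortest-product heuristic is applied.
#'
#' @param templates Tibble with `id`, `residues` (and optionally `role`).
#' @param forward,reverse One-row tibbles with `name`, `sequence` (both
#'   written 5'->3').
#' @param max_product_len Maximum product length, bp.
#' @param ... Passed to [find_primer_sites()] (mismatch stringency).
#' @return Tibble: `template_id`, `fwd_start`, `fwd_end`, `rev_start`,
#'   `rev_end`, `product_start`, `product_end`, `product_length`,
#'   `product_seq`.
#' @export
predict_amplicons <- function(templates, forward, reverse,
                              max_product_len = 10000L, ...) {
  fh <- find_primer_sites(templates, forward, ...) |> filter(.data$strand == "+")
  rh <- find_primer_sites(templates, reverse, ...) |> filter(.data$strand == "-")
  out <- list()
  for (i in seq_len(nrow(templates))) {
    id <- templates$id[i]
    f <- fh |> filter(.data$template_id == id)
    r <- rh |> filter(.data$template_id == id)
    if (nrow(f) == 0L || nrow(r) == 0L) next
    pairs <- tidyr::expand_grid(fi = seq_len(nrow(f)), ri = seq_len(nrow(r))) |>
      mutate(
        fwd_start = f$start[.data$fi], fwd_end = f$end[.data$fi],
        rev_start = r$start[.data$ri], rev_end = r$end[.data$ri]
      ) |>
      filter(.data$rev_start > .data$fwd_end,
             .data$rev_end - .data$fwd_start + 1L <= max_product_len)
    if (nrow(pairs) == 0L) next
    out[[length(out) + 1L]] <- pairs |>
      mutate(
        template_id = id,
        product_start = .data$fwd_start,
        product_end = .data$rev_end,
        product_length = .data$rev_end - .data$fwd_start + 1L,
        product_seq = substring(templates$residues[i],
                                .data$fwd_start, .data$rev_end)
      ) |>
      select("template_id", "fwd_start", "fwd_end", "rev_start", "rev_end",
             "product_start", "product_end", "product_length", "product_seq")
  }
  if (length(out)) bind_rows(out) else tibble(
    template_id = character(), fwd_start = integer(), fwd_end = integer(),
    rev_start = integer(), rev_end = integer(), product_start = integer(),
    product_end = integer(), product_length = integer(),
    product_seq = character()
  )
}

# Fewest mismatches of a clamp against a product over all ungapped offsets
# and both strands; Inf when the clamp is longer than the product.
clamp_best_mismatch <- function(product_seq, clamp_seq) {
  tch <- seq_chars(product_seq)
  best <- Inf
  for (q in c(clamp_seq, reverse_complement(clamp_seq))) {
    mm <- offset_mismatch_counts(tch, seq_chars(q))
    if (length(mm)) best <- min(best, min(mm))
  }
  best
}

#' Predict clamp blocking outcomes for amplicons
#'
#' A template's product is `blocked` when some clamp aligns inside it
#' (either strand, ungapped) with at most `block_max_mismatch` mismatches;
#' otherwise it remains `amplifiable`. The default threshold is 0: a single
#' mismatch destabilizes PNA/DNA hybrids enough to abolish clamping, which
#' is also what makes a 5-mismatch design margin safe for microbes.
#'
#' @param amplicons A [predict_amplicons()] result.
#' @param clamps Tibble with `name`, `sequence` (one row per clamp).
#' @param block_max_mismatch Mismatch tolerance for blocking.
#' @return `amplicons` with one `mm_<clamp>` column per clamp (best
#'   mismatch count inside the product) and `predicted_outcome`.
#' @export
predict_clamp_effect <- function(amplicons, clamps, block_max_mismatch = 0L) {
  out <- amplicons
  blocked <- rep(FALSE, nrow(out))
  for (k in seq_len(nrow(clamps))) {
    cseq <- canonicalize_seq(clamps$sequence[k])
    mm <- map_dbl(out$product_seq, clamp_best_mismatch, clamp_seq = cseq)
    out[[paste0("mm_", clamps$name[k])]] <- mm
    blocked <- blocked | mm <= block_max_mismatch
  }
  out$predicted_outcome <- ifelse(blocked, "blocked", "amplifiable")
  out
}

#' Predict pool composition under clamping
#'
#' Deterministic, weight-based bookkeeping of which templates remain
#' amplifiable once clamps are added: each template contributes its copy
#' weight if at least one of its predicted products escapes every clamp.
#' No PCR-efficiency or cycle kinetics are modeled.
#'
#' @param templates Tibble with `id`, `residues`, `role`, and `weight`
#'   (relative copy number, non-negative, not all zero).
#' @param forward,reverse Primer tibbles (see [predict_amplicons()]).
#' @param clamps Clamp tibble (`name`, `sequence`); may have zero rows.
#' @param block_max_mismatch Blocking mismatch tolerance.
#' @param ... Passed to [predict_amplicons()].
#' @return List of class `composition_prediction` with `composition`
#'   (tibble `role`, `weight`, `fraction` over amplifiable templates,
#'   summing to 1) and `per_template` (tibble `id`, `role`, `weight`,
#'   `outcome` in `{amplifiable, blocked, no_product}`). When every
#'   template is blocked or productless, `composition` is empty and a
#'   warning is raised.
#' @export
predict_composition <- function(templates, forward, reverse,
                                clamps = tibble(name = character(),
                                                sequence = character()),
                                block_max_mismatch = 0L, ...) {
  stopifnot(all(c("id", "residues", "role", "weight") %in% names(templates)),
            all(templates$weight >= 0), any(templates$weight > 0))
  amp <- predict_amplicons(templates, forward, reverse, ...)
  if (nrow(amp) && nrow(clamps)) {
    amp <- predict_clamp_effect(amp, clamps, block_max_mismatch)
  } else if (nrow(amp)) {
    amp$predicted_outcome <- "amplifiable"
  }
  outcome <- map_chr(templates$id, function(id) {
    sub <- amp[amp$template_id == id, , drop = FALSE]
    if (nrow(sub) == 0L) "no_product"
    else if (any(sub$predicted_outcome == "amplifiable")) "amplifiable"
    else "blocked"
  })
  per_template <- templates |>
    select("id", "role", "weight") |>
    mutate(outcome = outcome)
  ok <- per_template |> filter(.data$outcome == "amplifiable")
  if (nrow(ok) == 0L || sum(ok$weight) == 0) {
    warn("no amplifiable template weight; composition is empty")
    comp <- tibble(role = character(), weight = double(), fraction = double())
  } else {
    comp <- ok |>
      group_by(.data$role) |>
      summarise(weight = sum(.data$weight), .groups = "drop") |>
      mutate(fraction = .data$weight / sum(.data$weight))
  }
  structure(list(composition = comp, per_template = per_template),
            class = "composition_prediction")
}

#' @export
print.composition_prediction <- function(x, ...) {
  cat("<composition_prediction>\n")
  print(x$composition)
  cat("per-template outcomes:\n")
  print(table(x$per_template$outcome))
  invisible(x)
}
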