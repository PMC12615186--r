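check_alignment <- function(records) {
  stopifnot(all(c("id", "residues", "role") %in% names(records)))
  len <- nchar(records$residues)
  if (length(unique(len)) != 1L) {
    abort("aligned records must all have the same length")
  }
  if (!any(records$role == "host")) abort("alignment has no host records")
  if (!any(records$role == "microbe")) abort("alignment has no microbe records")
  invisible(len[1])
}

alignment_matrix <- function(records) {
  do.call(rbind, strsplit(records$residues, "", fixed = TRUE))
}

# Deterministic consensus tie-break: A < C < G < T < degenerate codes < gap
CONSENSUS_ORDER <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                     "B", "D", "H", "V", "N", "-")

#' Build a per-column host/microbe conservation profile
#'
#' For every alignment column the profile records the host consensus
#' residue (strict plurality over host rows, ties broken in fixed base
#' order A < C < G < T), the fraction of host rows carrying that consensus,
#' host and microbe gap fractions, and the microbial base frequencies. This
#' is the substrate on which clamp sites — host-conserved, microbe-divergent
#' — are located.
#'
#' @param records Aligned sequence tibble (equal-length `residues`, with at
#'   least one `host` and one `microbe` role).
#' @return A tibble of class `conservation_profile` with one row per column:
#'   `column`, `host_consensus`, `host_conservation`, `host_gap_fraction`,
#'   `microbe_gap_fraction`, and a list-column `microbe_freqs` of named
#'   base-frequency vectors (gap excluded; frequencies plus
#'   `microbe_gap_fraction` sum to 1). The host/microbe row counts are
#'   attached as attributes `n_host` / `n_microbe`.
#' @export
build_profile <- function(records) {
  check_alignment(records)
  mat <- alignment_matrix(records)
  host <- mat[records$role == "host", , drop = FALSE]
  microbe <- mat[records$role == "microbe", , drop = FALSE]
  n_host <- nrow(host); n_microbe <- nrow(microbe)
  n_col <- ncol(mat)

  cons <- character(n_col); consv <- numeric(n_col)
  hgap <- numeric(n_col); mgap <- numeric(n_col)
  mfreq <- vector("list", n_col)
  for (j in seq_len(n_col)) {
    hcol <- host[, j]
    tab <- table(factor(hcol, levels = CONSENSUS_ORDER))
    best <- names(tab)[which.max(tab)] # which.max takes first on ties
    cons[j] <- best
    consv[j] <- tab[[best]] / n_host
    hgap[j] <- mean(hcol == "-")
    mcol <- microbe[, j]
    mgap[j] <- mean(mcol == "-")
    bt <- table(mcol[mcol != "-"]) / n_microbe
    mfreq[[j]] <- stats::setNames(as.numeric(bt), names(bt))
  }
  out <- tibble(
    column = seq_len(n_col),
    host_consensus = cons,
    host_conservation = consv,
    host_gap_fraction = hgap,
    microbe_gap_fraction = mgap,
    microbe_freqs = mfreq
  )
  attr(out, "n_host") <- n_host
  attr(out, "n_microbe") <- n_microbe
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Locate host-conserved, gap-free column blocks
#'
#' Maximal runs of columns whose host conservation meets the threshold and
#' in which no host row has a gap — a clamp must bind every host haplotype,
#' so any host gap disqualifies the column. "Strictly conserved" is the
#' default (`min_conservation = 1`); relax it only for degraded reference
#' sets.
#'
#' @param profile A [build_profile()] result.
#' @param min_conservation Minimum host conservation per column, in (0, 1].
#' @param min_len Minimum block length, columns.
#' @return Tibble with 1-based inclusive `start`, `end`, `length`, and the
#'   host sequence count `n_host` the call was based on.
#' @export
host_conserved_blocks <- function(profile, min_conservation = 1, min_len = 12L) {
  stopifnot(min_conservation > 0, min_conservation <= 1, min_len >= 1)
  ok <- profile$host_conservation >= min_conservation &
    profile$host_gap_fraction == 0
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble(
    start = starts[keep],
    end = ends[keep],
    length = r$lengths[keep],
    n_host = attr(profile, "n_host") %||% NA_integer_
  )
}

#' Map alignment columns to ungapped positions on one host sequence
#'
#' @param records Aligned sequence tibble.
#' @param host_id Id of the reference record.
#' @param column Integer vector of 1-based alignment columns.
#' @return Integer vector of 1-based ungapped positions on the named
#'   sequence; `NA` where the record has a gap at that column.
#' @export
column_to_host_coordinate <- function(records, host_id, column) {
  row <- records[records$id == host_id, ]
  if (nrow(row) != 1L) abort(sprintf("unknown record id '%s'", host_id))
  ch <- seq_chars(row$residues)
  stopifnot(all(column >= 1L), all(column <= length(ch)))
  pos <- cumsum(ch != "-")
  ifelse(ch[column] == "-", NA_integer_, pos[column])
}

#' Map ungapped host positions back to alignment columns
#'
#' Inverse of [column_to_host_coordinate()] on non-gap columns.
#'
#' @inheritParams column_to_host_coordinate
#' @param position Integer vector of 1-based ungapped positions.
#' @return Integer vector of alignment columns.
#' @export
host_coordinate_to_column <- function(records, host_id, position) {
  row <- records[records$id == host_id, ]
  if (nrow(row) != 1L) abort(sprintf("unknown record id '%s'", host_id))
  ch <- seq_chars(row$residues)
  cols <- which(ch != "-")
  stopifnot(all(position >= 1L), all(position <= length(cols)))
  cols[position]
}

#' Host consensus sequence from a profile
#'
#' Concatenates the per-column host consensus, optionally dropping columns
#' whose consensus is a gap, and keeps the column map so hits on the
#' degapped string can be projected back onto alignment columns.
#'
#' @param profile A [build_profile()] result.
#' @param degap Drop gap-consensus columns?
#' @return List with `sequence` (string) and `columns` (alignment column of
#'   each residue of `sequence`).
#' @export
consensus_sequence <- function(profile, degap = TRUE) {
  keep <- if (degap) profile$host_consensus != "-" else
    rep(TRUE, nrow(profile))
  list(sequence = paste(profile$host_consensus[keep], collapse = ""),
       columns = profile$column[keep])
}

#' Flatten a conservation profile for TSV export
#'
#' Expands the `microbe_freqs` list-column into `microbe_A` .. `microbe_T`
#' (plus any degenerate codes observed) so the profile can be written with
#' [readr::write_tsv()].
#'
#' @param profile A [build_profile()] result.
#' @return A plain tibble with one numeric column per observed microbe base.
#' @export
flatten_profile <- function(profile) {
  bases <- sort(unique(unlist(map(profile$microbe_freqs, names))))
  freq_cols <- map(bases, function(b) {
    map_dbl(profile$microbe_freqs, ~ .x[b] %||% 0)
  })
  names(freq_cols) <- paste0("microbe_", bases)
  dplyr::bind_cols(
    profile |> select(-"microbe_freqs") |> as_tibble(),
    tibble::new_tibble(freq_cols, nrow = nrow(profile))
  )
}

#' @rdname autoplot.conservation_profile
#' @export
plot_profile <- function(object, ...) autoplot.conservation_profile(object, ...)

#' Plot host conservation and microbe divergence along the alignment
#'
#' @param object A [build_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, ...) {
  df <- tibble(
    column = object$column,
    host_conservation = object$host_conservation,
    microbe_gap = object$microbe_gap_fraction
  ) |>
    tidyr::pivot_longer(-"column", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$column, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "alignment column", y = "fraction", colour = NULL) +
    ggplot2::theme_minimal()
}
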