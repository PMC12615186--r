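# Average mass of one double-stranded base pair: 650 g/mol / Avogadro, in ng.
MASS_PER_BP_NG <- 650 / 6.02214076e23 * 1e9

#' Marker-gene copies per microliter of a DNA extract
#'
#' Standard genome-equivalent calculation: the number of genome copies in
#' one microliter (mass divided by genome mass) times the marker copies
#' carried per genome. This is the quantity equalized across members when
#' assembling a copy-number balanced mock community.
#'
#' @param members Tibble with columns `name`, `dna_concentration` (ng/uL),
#'   `genome_length` (bp), `marker_copies_per_genome`.
#' @param mass_per_bp Mass of one base pair in ng (default: 650 g/mol per
#'   bp over Avogadro's number, about 1.0794e-12 ng).
#' @return The input with a `copies_per_ul` column.
#' @examples
#' marker_copies_per_microliter(tibble::tibble(
#'   name = "sp1", dna_concentration = 10,
#'   genome_length = 4e6, marker_copies_per_genome = 4
#' ))
#' @export
marker_copies_per_microliter <- function(members,
                                         mass_per_bp = MASS_PER_BP_NG) {
  stopifnot(all(c("name", "dna_concentration", "genome_length",
                  "marker_copies_per_genome") %in% names(members)))
  if (any(members$dna_concentration <= 0) || any(members$genome_length <= 0) ||
      any(members$marker_copies_per_genome <= 0) || mass_per_bp <= 0) {
    abort("all mock-member quantities must be positive")
  }
  members |>
    mutate(copies_per_ul = .data$dna_concentration /
             (.data$genome_length * mass_per_bp) *
             .data$marker_copies_per_genome)
}

#' Pipetting volumes for a copy-number balanced mock community
#'
#' Chooses per-member volumes so every species contributes the same number
#' of marker-gene copies to the final mix (expected copy fraction `1/n`
#' each).
#'
#' @inheritParams marker_copies_per_microliter
#' @param target_copies Marker copies contributed per member.
#' @return A `mock_recipe` tibble: `name`, `copies_per_ul`, `volume_ul`,
#'   `expected_copy_fraction`, `total_copies`.
#' @export
balanced_volumes <- function(members, target_copies = 1e7,
                             mass_per_bp = MASS_PER_BP_NG) {
  stopifnot(nrow(members) >= 2L, target_copies > 0)
  m <- marker_copies_per_microliter(members, mass_per_bp)
  if (any(m$copies_per_ul <= 0)) {
    abort(sprintf("member '%s' yields zero marker copies",
                  m$name[m$copies_per_ul <= 0][1]))
  }
  out <- m |>
    mutate(volume_ul = target_copies / .data$copies_per_ul,
           total_copies = .data$volume_ul * .data$copies_per_ul,
           expected_copy_fraction = .data$total_copies /
             sum(.data$total_copies)) |>
    select("name", "copies_per_ul", "volume_ul",
           "expected_copy_fraction", "total_copies")
  class(out) <- c("mock_recipe", class(out))
  out
}

#' Pipetting volumes for an unbalanced mock community
#'
#' Chooses volumes so the expected marker-copy fractions equal a given
#' target profile (e.g. to emulate a skewed community as an inhibition
#' control for low-abundance taxa).
#'
#' @inheritParams balanced_volumes
#' @param target_fractions Numeric vector, one per member, summing to 1;
#'   zero is not allowed (omit the member instead).
#' @param total_copies Total marker copies in the final mix.
#' @return A `mock_recipe` tibble (see [balanced_volumes()]).
#' @export
unbalanced_volumes <- function(members, target_fractions,
                               total_copies = 1e8,
                               mass_per_bp = MASS_PER_BP_NG) {
  stopifnot(length(target_fractions) == nrow(members))
  if (abs(sum(target_fractions) - 1) > 1e-9) {
    abort("target fractions must sum to 1")
  }
  if (any(target_fractions <= 0)) {
    abort("target fraction 0 for a listed member: omit the member instead")
  }
  m <- marker_copies_per_microliter(members, mass_per_bp)
  out <- m |>
    mutate(target_fraction = target_fractions,
           volume_ul = .data$target_fraction * total_copies /
             .data$copies_per_ul,
           total_copies = .data$volume_ul * .data$copies_per_ul,
           expected_copy_fraction = .data$total_copies /
             sum(.data$total_copies)) |>
    select("name", "copies_per_ul", "volume_ul",
           "expected_copy_fraction", "total_copies")
  class(out) <- c("mock_recipe", class(out))
  out
}

#' Compare observed read fractions to expected copy fractions
#'
#' Harmonizes the taxon universes (observed taxa absent from the expected
#' profile are grouped as `"other"`), then reports per-taxon log2
#' observed/expected ratios (with a pseudo-fraction for zeros), the L1
#' distance between the two profiles, and the expected-but-undetected
#' taxa.
#'
#' @param observed Tibble with `taxon` and `fraction` (read fractions).
#' @param expected Tibble with `taxon` and `fraction` (copy fractions,
#'   summing to 1).
#' @param pseudo Pseudo-fraction substituted for zeros in log ratios.
#' @return List of class `mock_comparison`: `per_taxon` (tibble with
#'   `taxon`, `observed`, `expected`, `log2_ratio`), `l1_distance` (in
#'   `[0, 2]`), `undetected` (character vector).
#' @export
compare_observed_expected <- function(observed, expected, pseudo = 1e-6) {
  stopifnot(all(c("taxon", "fraction") %in% names(observed)),
            all(c("taxon", "fraction") %in% names(expected)))
  if (abs(sum(expected$fraction) - 1) > 1e-9) {
    abort("expected fractions must sum to 1")
  }
  obs <- observed |>
    mutate(taxon = ifelse(.data$taxon %in% expected$taxon,
                          .data$taxon, "other")) |>
    group_by(.data$taxon) |>
    summarise(observed = sum(.data$fraction), .groups = "drop")
  exp_tbl <- expected |>
    group_by(.data$taxon) |>
    summarise(expected = sum(.data$fraction), .groups = "drop")
  per <- dplyr::full_join(exp_tbl, obs, by = "taxon") |>
    mutate(observed = dplyr::coalesce(.data$observed, 0),
           expected = dplyr::coalesce(.data$expected, 0),
           log2_ratio = log2(pmax(.data$observed, pseudo) /
                               pmax(.data$expected, pseudo)))
  structure(
    list(
      per_taxon = per,
      l1_distance = sum(abs(per$observed - per$expected)),
      undetected = per$taxon[per$expected > 0 & per$observed == 0]
    ),
    class = "mock_comparison"
  )
}

#' @export
print.mock_comparison <- function(x, ...) {
  cat("<mock_comparison>\n")
  print(x$per_taxon)
  cat(sprintf("L1 distance: %.4g\n", x$l1_distance))
  if (length(x$undetected)) {
    cat("undetected:", paste(x$undetected, collapse = ", "), "\n")
  }
  invisible(x)
}
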