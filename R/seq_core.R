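#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number desc across
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap
#' @keywords internal
"_PACKAGE"

# IUPAC nucleotide code -> set of concrete bases
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
IUPAC_CODES <- names(IUPAC_SETS)

# Precomputed 15x15 set-intersection table, used by every mismatch scan.
IUPAC_MATCH_MATRIX <- local({
  m <- matrix(FALSE, 15L, 15L, dimnames = list(IUPAC_CODES, IUPAC_CODES))
  for (a in IUPAC_CODES) for (b in IUPAC_CODES) {
    m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L
  }
  m
})

#' Split a sequence string into a character vector of single residues
#' @noRd
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Validate and canonicalize an IUPAC DNA string
#'
#' Uppercases, maps U to T, and checks every residue against the IUPAC DNA
#' alphabet. Gaps (`-`) are only admitted when `allow_gaps = TRUE` (aligned
#' context).
#'
#' @param seq A single DNA string.
#' @param allow_gaps Admit `-` characters (aligned sequences)?
#' @param what Label used in error messages (e.g. a record id).
#' @return The canonical uppercase string.
#' @export
canonicalize_seq <- function(seq, allow_gaps = FALSE, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  if (!nzchar(s)) abort(sprintf("%s is empty", what))
  allowed <- c(IUPAC_CODES, if (allow_gaps) "-")
  ch <- seq_chars(s)
  bad <- which(!ch %in% allowed)
  if (length(bad)) {
    abort(sprintf(
      "illegal character '%s' at position %d in %s", ch[bad[1]], bad[1], what
    ))
  }
  s
}

#' Read a multi-FASTA file into a sequence record tibble
#'
#' Each record carries a host/microbe role used by the design machinery. The
#' role is parsed from a header token (default: an id suffix `|host` or
#' `|microbe`); a two-column TSV role map (`id`, `role`) overrides headers.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param role_map Optional path to a TSV with columns `id` and `role`, or a
#'   data frame with those columns.
#' @param allow_gaps Admit `-` (aligned FASTA)?
#' @return A tibble with columns `id`, `description`, `residues`, `role`
#'   (one of `"host"`, `"microbe"`, `"unknown"`).
#' @examples
#' tmp <- tempfile(fileext = ".fasta")
#' writeLines(c(">wheat_chl|host", "ACGTACGT", ">bact1|microbe", "ACGAACGA"), tmp)
#' read_fasta(tmp)
#' @export
read_fasta <- function(path, role_map = NULL, allow_gaps = TRUE) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("no FASTA records in '%s'", path))
  headers <- names(set)
  name <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  role <- rep("unknown", length(name))
  has_tag <- grepl("\\|(host|microbe)$", name, ignore.case = TRUE)
  role[has_tag] <- tolower(sub("^.*\\|", "", name[has_tag]))
  id <- sub("\\|(host|microbe)$", "", name, ignore.case = TRUE)
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate record id '%s'", id[duplicated(id)][1]))
  }
  residues <- map_chr(seq_along(set), function(i) {
    canonicalize_seq(as.character(set[[i]]), allow_gaps = allow_gaps,
                     what = sprintf("record '%s'", id[i]))
  })
  records <- tibble(id = id, description = description,
                    residues = residues, role = role)
  if (!is.null(role_map)) {
    rm_tbl <- if (is.data.frame(role_map)) {
      as_tibble(role_map)
    } else {
      readr::read_tsv(role_map, col_types = readr::cols(.default = "c"))
    }
    stopifnot(all(c("id", "role") %in% names(rm_tbl)))
    bad <- setdiff(unique(rm_tbl$role), c("host", "microbe", "unknown"))
    if (length(bad)) abort(sprintf("unknown role '%s' in role map", bad[1]))
    records <- records |>
      left_join(rm_tbl |> select("id", map_role = "role"), by = "id") |>
      mutate(role = dplyr::coalesce(.data$map_role, .data$role)) |>
      select(-"map_role")
  }
  records
}

#' Write a sequence record tibble to FASTA
#'
#' Roles are serialized as the `|host` / `|microbe` id suffix so that a
#' write-then-read round trip reproduces the collection.
#'
#' @param records Tibble as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "residues", "role") %in% names(records)))
  tag <- ifelse(records$role %in% c("host", "microbe"),
                paste0("|", records$role), "")
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- paste0(records$id, tag,
                ifelse(nzchar(desc), paste0(" ", desc), ""))
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Do two IUPAC bases share at least one concrete base?
#'
#' Vectorized over both arguments. `N` matches everything; disjoint codes
#' (e.g. `A` vs `G`) do not match. Symmetric by construction.
#'
#' @param a,b Character vectors of single IUPAC DNA codes (no gaps).
#' @return Logical vector.
#' @examples
#' iupac_match("M", "A") # TRUE: M = {A,C}
#' iupac_match("A", "G") # FALSE
#' @export
iupac_match <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  bad <- c(a, b)[!c(a, b) %in% IUPAC_CODES]
  if (length(bad)) {
    abort(sprintf("'%s' is not an IUPAC base (gaps are not comparable)", bad[1]))
  }
  IUPAC_MATCH_MATRIX[cbind(a, b)]
}

#' Reverse complement of an IUPAC DNA string
#'
#' The complement is extended to degenerate codes (R<->Y, K<->M, B<->V,
#' D<->H; S, W, N are self-complementary). Applying it twice returns the
#' input.
#'
#' @param seq Character vector of IUPAC DNA strings (no gaps).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT") # "ACGT"
#' reverse_complement("M")    # "K"
#' @export
reverse_complement <- function(seq) {
  map_chr(seq, function(s) {
    rc_fast(canonicalize_seq(s, allow_gaps = FALSE))
  })
}

# validation-free reverse complement for hot loops
rc_fast <- function(s) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
  paste(rev(seq_chars(comp)), collapse = "")
}

check_concrete <- function(seq, what) {
  s <- canonicalize_seq(seq, allow_gaps = FALSE, what = what)
  ch <- seq_chars(s)
  deg <- which(!ch %in% c("A", "C", "G", "T"))
  if (length(deg)) {
    abort(sprintf(
      "%s contains degenerate base '%s' at position %d; resolve it first",
      what, ch[deg[1]], deg[1]
    ))
  }
  ch
}

#' Purine fraction of a concrete oligomer
#'
#' Computed on the oligomer as synthesized (the 5'->3' strand), matching how
#' clamp sequences are reported. PNA design practice keeps this below 50%.
#'
#' @param seq A non-degenerate, ungapped DNA string.
#' @return `(#A + #G) / length`, in `[0, 1]`.
#' @examples
#' purine_fraction("CCCACGGAGACCTACCT") # 7/17
#' @export
purine_fraction <- function(seq) {
  ch <- check_concrete(seq, "purine_fraction() input")
  sum(ch %in% c("A", "G")) / length(ch)
}

#' Longest contiguous purine run in a concrete oligomer
#'
#' Runs of more than four purines destabilize PNA synthesis and solubility,
#' so candidate clamps are screened against them.
#'
#' @inheritParams purine_fraction
#' @return Integer run length; 0 for purine-free sequences.
#' @examples
#' max_purine_run("CCCACGGAGACCTACCT") # 5 (GGAGA)
#' @export
max_purine_run <- function(seq) {
  ch <- check_concrete(seq, "max_purine_run() input")
  is_pur <- ch %in% c("A", "G")
  if (!any(is_pur)) return(0L)
  r <- rle(is_pur)
  max(r$lengths[r$values])
}

#' Longest self-complementary stretch within an oligomer
#'
#' Finds the longest `L` such that some `L`-mer of the sequence equals the
#' reverse complement of some (possibly the same) `L`-mer, i.e. the longest
#' potential intra-/inter-molecular hairpin or dimer stem. Degenerate codes
#' are compared literally (an `L`-mer matches only its exact IUPAC reverse
#' complement).
#'
#' @param seq Ungapped DNA string.
#' @param k Minimum stretch length considered problematic (default 4).
#' @return A list with elements `length` (the longest `L`, 0 if none) and
#'   `flagged` (`length >= k`).
#' @examples
#' self_complementary_stretch("GAATTC", k = 4) # full 6-mer palindrome
#' @export
self_complementary_stretch <- function(seq, k = 4L) {
  s <- canonicalize_seq(seq, allow_gaps = FALSE,
                        what = "self_complementary_stretch() input")
  stopifnot(k >= 3L)
  n <- nchar(s)
  best <- 0L
  for (L in seq(n, 1L)) {
    starts <- seq_len(n - L + 1L)
    mers <- substring(s, starts, starts + L - 1L)
    rcs <- vapply(mers, rc_fast, character(1), USE.NAMES = FALSE)
    if (any(rcs %in% mers)) { best <- L; break }
  }
  list(length = best, flagged = best >= k)
}

#' Expand a degenerate IUPAC sequence into concrete variants
#'
#' @param seq IUPAC DNA string (no gaps).
#' @param max_variants Safety cap on the expansion size.
#' @return Character vector of concrete ACGT sequences.
#' @export
expand_degenerate <- function(seq, max_variants = 4096L) {
  s <- canonicalize_seq(seq, allow_gaps = FALSE)
  sets <- IUPAC_SETS[seq_chars(s)]
  n_var <- prod(lengths(sets))
  if (n_var > max_variants) {
    abort(sprintf("degenerate expansion has %d variants (cap %d)",
                  n_var, max_variants))
  }
  grid <- do.call(expand.grid,
                  c(unname(sets), list(stringsAsFactors = FALSE)))
  apply(grid, 1L, paste0, collapse = "")
}
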