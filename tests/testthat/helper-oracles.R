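# Independent brute-force oracles. These deliberately avoid the package's
# internal lookup tables: IUPAC semantics are re-derived from base sets.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_base_match <- function(a, b) {
  length(intersect(ORACLE_SETS[[a]], ORACLE_SETS[[b]])) > 0
}

oracle_revcomp <- function(s) {
  comp_one <- function(ch) {
    set <- ORACLE_SETS[[ch]]
    comp_set <- sort(chartr("ACGT", "TGCA", set))
    for (code in names(ORACLE_SETS)) {
      if (identical(sort(ORACLE_SETS[[code]]), comp_set)) return(code)
    }
    stop("no code")
  }
  ch <- strsplit(s, "")[[1]]
  paste(rev(vapply(ch, comp_one, character(1))), collapse = "")
}

# quadratic all-pairs L-mer scan
oracle_self_comp <- function(s, k) {
  n <- nchar(s)
  best <- 0L
  for (L in seq_len(n)) {
    starts <- seq_len(n - L + 1L)
    mers <- substring(s, starts, starts + L - 1L)
    rcs <- vapply(mers, oracle_revcomp, character(1))
    hit <- outer(mers, rcs, "==") # all pairs
    if (any(hit)) best <- L
  }
  list(length = best, flagged = best >= k)
}

# all-position primer scan, both strands
oracle_primer_scan <- function(template, primer, max_mismatch = 2L,
                               three_prime_window = 5L, three_prime_max = 0L) {
  tch <- strsplit(template, "")[[1]]
  m <- nchar(primer)
  w <- min(three_prime_window, m)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") primer else oracle_revcomp(primer)
    qch <- strsplit(q, "")[[1]]
    tp_idx <- if (strand == "+") seq(m - w + 1L, m) else seq_len(w)
    for (s in seq_len(length(tch) - m + 1L)) {
      mm <- 0L; tp <- 0L
      for (j in seq_len(m)) {
        if (!oracle_base_match(qch[j], tch[s + j - 1L])) {
          mm <- mm + 1L
          if (j %in% tp_idx) tp <- tp + 1L
        }
      }
      if (mm <= max_mismatch && tp <= three_prime_max) {
        hits[[length(hits) + 1L]] <-
          data.frame(strand = strand, start = s, end = s + m - 1L,
                     mismatches = mm, three_prime_mismatch = tp > 0L)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(strand = character(), start = integer(), end = integer(),
               mismatches = integer(), three_prime_mismatch = logical())
}

# position-by-position clamp-vs-microbe mismatch count over alignment cols
oracle_site_mismatches <- function(site_seq, microbe_residues, start, end) {
  site <- strsplit(site_seq, "")[[1]]
  res <- strsplit(microbe_residues, "")[[1]][start:end]
  mm <- 0L
  for (i in seq_along(site)) {
    if (res[i] == "-" || !oracle_base_match(site[i], res[i])) mm <- mm + 1L
  }
  mm
}

random_iupac_string <- function(n, degenerate = FALSE) {
  pool <- if (degenerate) names(ORACLE_SETS) else c("A", "C", "G", "T")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# hand-built toy alignment: hosts conserved only on [block_start, block_end],
# microbes diverge from the host site by >= n_mm positions inside it
toy_alignment <- function(n_host = 3L, n_microbe = 4L, n_col = 60L,
                          block_start = 21L, block_end = 45L, n_mm = 5L,
                          seed = 42L) {
  withr::with_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), n_col, replace = TRUE)
    block <- block_start:block_end
    hosts <- lapply(seq_len(n_host), function(i) {
      ch <- base
      outside <- setdiff(seq_len(n_col), block)
      flip <- outside[seq(i, length(outside), by = n_host)]
      for (p in flip) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      ch
    })
    microbes <- lapply(seq_len(n_microbe), function(i) {
      ch <- base
      mut <- sample(block, n_mm)
      for (p in mut) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      ch
    })
    tibble::tibble(
      id = c(sprintf("h%d", seq_len(n_host)), sprintf("m%d", seq_len(n_microbe))),
      description = "",
      residues = vapply(c(hosts, microbes), paste, character(1), collapse = ""),
      role = c(rep("host", n_host), rep("microbe", n_microbe))
    )
  })
}

v5v7_primers <- function() {
  wheat_clamp_oligos() |>
    dplyr::filter(name %in% c("799F", "1193R")) |>
    dplyr::select(name, sequence, orientation)
}
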