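# Unified DNA/DNA nearest-neighbor parameters (Allawi & SantaLucia 1997 /
# SantaLucia 1998 "unified" set). dh in kcal/mol, ds in cal/(mol K).
NN_UNIFIED <- list(
  stack = list(
    AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9),
    # complements
    TT = c(-7.9, -22.2), TG = c(-8.5, -22.7), AC = c(-8.4, -22.4),
    AG = c(-7.8, -21.0), TC = c(-8.2, -22.2), CC = c(-8.0, -19.9)
  ),
  init_AT = c(2.3, 4.1),   # per A/T terminal base pair
  init_GC = c(0.1, -2.8)   # per G/C terminal base pair
)

#' Thermodynamic configuration for Tm estimation
#'
#' Bundles the nearest-neighbor parameter choice, solution conditions, and
#' the PNA/DNA Tm correlation coefficients, together with the two reference
#' temperatures a clamp must clear: the PCR extension temperature (a clamp
#' must stay annealed while the polymerase extends) and the PNA target Tm
#' (clamps are designed to melt as close to 80 degrees C as possible, well
#' above extension).
#'
#' @param nn_table Nearest-neighbor table identifier (only
#'   `"unified"` — the SantaLucia unified DNA/DNA set — is shipped).
#' @param monovalent_salt Monovalent cation concentration, molar.
#' @param oligo_concentration Total oligonucleotide concentration, molar.
#' @param pna_coefficients Numeric `(c0, c1, c2, c3)` of the linear PNA/DNA
#'   Tm correlation `c0 + c1 * Tm_dna + c2 * f_pyrimidine + c3 * length`.
#' @param extension_temperature PCR extension temperature, degrees C.
#' @param pna_target_tm Design target for PNA Tm, degrees C.
#' @param degenerate_mode How degenerate primers are resolved before Tm
#'   calculation: `"max"` (most stable expansion; the variant that governs
#'   annealing feasibility), `"min"`, or `"mean"`.
#' @return An object of class `thermo_config`.
#' @export
thermo_config <- function(nn_table = "unified",
                          monovalent_salt = 0.05,
                          oligo_concentration = 250e-9,
                          pna_coefficients = c(20.79, 0.83, -26.13, 0.44),
                          extension_temperature = 72,
                          pna_target_tm = 80,
                          degenerate_mode = c("max", "min", "mean")) {
  degenerate_mode <- match.arg(degenerate_mode)
  stopifnot(
    identical(nn_table, "unified"),
    monovalent_salt > 0, oligo_concentration > 0,
    length(pna_coefficients) == 4L,
    extension_temperature < pna_target_tm
  )
  structure(
    list(nn_table = nn_table,
         monovalent_salt = monovalent_salt,
         oligo_concentration = oligo_concentration,
         pna_coefficients = pna_coefficients,
         extension_temperature = extension_temperature,
         pna_target_tm = pna_target_tm,
         degenerate_mode = degenerate_mode),
    class = "thermo_config"
  )
}

#' @export
print.thermo_config <- function(x, ...) {
  cat("<thermo_config>\n")
  cat(sprintf("  nn_table:              %s\n", x$nn_table))
  cat(sprintf("  monovalent_salt:       %g M\n", x$monovalent_salt))
  cat(sprintf("  oligo_concentration:   %g M\n", x$oligo_concentration))
  cat(sprintf("  pna_coefficients:      (%s)\n",
              paste(format(x$pna_coefficients), collapse = ", ")))
  cat(sprintf("  extension_temperature: %g C\n", x$extension_temperature))
  cat(sprintf("  pna_target_tm:         %g C\n", x$pna_target_tm))
  cat(sprintf("  degenerate_mode:       %s\n", x$degenerate_mode))
  invisible(x)
}

#' Wallace (2+4) rule melting temperature
#'
#' Quick additive estimate: 2 degrees per A/T, 4 per G/C. Only a fallback
#' for very short oligos; the nearest-neighbor model is preferred.
#'
#' @param seq Non-degenerate, ungapped DNA string.
#' @return Tm in degrees C.
#' @export
tm_wallace <- function(seq) {
  ch <- check_concrete(seq, "tm_wallace() input")
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

# flat lookup vectors for the hot path
NN_DH <- vapply(NN_UNIFIED$stack, `[`, numeric(1), 1L)
NN_DS <- vapply(NN_UNIFIED$stack, `[`, numeric(1), 2L)

tm_nn_concrete <- function(s, config) {
  ch <- seq_chars(s)
  n <- length(ch)
  pairs <- paste0(ch[-n], ch[-1L])
  dh <- sum(NN_DH[pairs])
  ds <- sum(NN_DS[pairs])
  for (term in ch[c(1L, n)]) {
    init <- if (term %in% c("A", "T")) NN_UNIFIED$init_AT else NN_UNIFIED$init_GC
    dh <- dh + init[1]; ds <- ds + init[2]
  }
  # entropy salt correction, 0.368 * (N-1) * ln[Na+]
  ds_salt <- ds + 0.368 * (n - 1) * log(config$monovalent_salt)
  r_gas <- 1.987 # cal/(mol K)
  k_eff <- config$oligo_concentration / 4 # non-self-complementary duplex
  1000 * dh / (ds_salt + r_gas * log(k_eff)) - 273.15
}

#' Nearest-neighbor DNA/DNA duplex melting temperature
#'
#' Standard enthalpy/entropy sum over dinucleotide stacks with terminal
#' initiation penalties, an entropic monovalent-salt correction, and the
#' oligo-concentration term. Degenerate bases are resolved according to
#' `config$degenerate_mode` (default: the most stable concrete expansion,
#' since for blocking purposes annealing is governed by the strongest
#' variant).
#'
#' @param seq Ungapped IUPAC DNA string, at least 8 nt.
#' @param config A [thermo_config()].
#' @return Tm in degrees C.
#' @examples
#' tm_dna_nn("ACGTCATCCCCACCTTCC")
#' @export
tm_dna_nn <- function(seq, config = thermo_config()) {
  s <- canonicalize_seq(seq, allow_gaps = FALSE, what = "tm_dna_nn() input")
  if (nchar(s) < 8L) {
    abort("tm_dna_nn() needs at least 8 nt; the NN model is unreliable below that")
  }
  variants <- expand_degenerate(s)
  tms <- map_dbl(variants, tm_nn_concrete, config = config)
  switch(config$degenerate_mode,
         max = max(tms), min = min(tms), mean = mean(tms))
}

#' PNA/DNA duplex melting temperature
#'
#' Sequence-based linear correlation on top of the DNA/DNA nearest-neighbor
#' Tm: `c0 + c1 * Tm_dna + c2 * f_pyr + c3 * n`, where `f_pyr` is the
#' pyrimidine fraction of the PNA and `n` its length. With the default
#' coefficients, pyrimidine-rich clamps melt above the corresponding
#' DNA/DNA duplex — the reason PNA clamps out-compete primers on host
#' templates.
#'
#' @param seq Non-degenerate, ungapped DNA string of length 6-30 (the PNA
#'   sequence written as DNA).
#' @param config A [thermo_config()].
#' @return Tm in degrees C.
#' @examples
#' tm_pna("CCCACGGAGACCTACCT")
#' @export
tm_pna <- function(seq, config = thermo_config()) {
  ch <- check_concrete(seq, "tm_pna() input")
  n <- length(ch)
  if (n < 6L || n > 30L) {
    abort(sprintf("tm_pna() supports lengths 6-30, got %d", n))
  }
  f_pyr <- 1 - sum(ch %in% c("A", "G")) / n
  co <- config$pna_coefficients
  # NN model needs >= 8 nt; pad is not meaningful, so reuse Wallace below 8
  tm_dna <- if (n >= 8L) tm_dna_nn(paste(ch, collapse = ""), config)
            else tm_wallace(paste(ch, collapse = ""))
  co[1] + co[2] * tm_dna + co[3] * f_pyr + co[4] * n
}
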