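---
title: "Designing PCR clamps to deplete host DNA in amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing PCR clamps to deplete host DNA in amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampdesign)
library(dplyr)
```

## The problem

Endophytic microbial communities are profiled by amplicon high-throughput
sequencing of a marker locus — hypervariable regions of the bacterial 16S
rRNA gene, or the fungal ITS1/ITS2 spacers. When the template is total DNA
extracted from plant tissue, most of it is plant DNA, and the plant's own
homologous loci (chloroplast 16S, mitochondrial 18S, nuclear ITS) are
co-amplified by the same "universal" primers. The result is a sequencing
run saturated with host reads and a microbial community profile that is
shallow, biased, or unusable.

PCR clamps suppress this at the amplification step. A clamp is an oligomer
that hybridizes to the host template inside the amplified region and
prevents its amplification, while binding microbial templates poorly
enough to leave them untouched. Two chemistries are supported here:

* **PNA clamps** — peptide nucleic acids, whose uncharged backbone gives
  PNA/DNA duplexes a higher melting temperature than the corresponding
  DNA/DNA duplex and makes them exquisitely mismatch-sensitive. PNAs are
  not extendable by polymerases, so wherever they sit (over a primer site
  or mid-amplicon) they block amplification of the template they bind.
* **Blocking primers** — ordinary oligonucleotides carrying a 3' C3
  spacer (a propyl group) that prevents extension. They are cheaper and
  are placed either *competitively* (overlapping a PCR primer's binding
  site, out-competing it on host templates) or for *elongation arrest*
  (between the two primer sites, stalling the polymerase).

The design problem is therefore a sequence-search problem: find a site
that is **strictly conserved across host reference sequences** and
**divergent from every microbial reference**, then verify that the
oligomer built on that site is thermodynamically and compositionally
workable.

## The design procedure

Given a pre-computed multiple alignment of host and microbial reference
sequences (the package deliberately does not align — aligner choice is
orthogonal, and any standard tool such as MAFFT works):

1. `build_profile()` tallies each alignment column: the host consensus
   residue, the fraction of host rows carrying it, host and microbe gap
   fractions, and microbial base frequencies.
2. `host_conserved_blocks()` extracts maximal runs of columns with host
   conservation at or above a threshold (default 1.0 — "strictly
   conserved") and no host gap. A clamp must bind every host haplotype,
   so a single host gap disqualifies a column.
3. `enumerate_pna_candidates()` slides windows of every allowed length
   (default 12–21 nt) over those blocks, on both strands, and annotates
   each window with:
   * predicted PNA/DNA melting temperature (`tm_pna`),
   * purine fraction and longest purine run,
   * longest self-complementary stretch,
   * which design guidelines the window breaches.
4. `score_candidates()` counts, for each candidate and each microbial
   row, the positions where the clamp cannot pair: disjoint IUPAC base
   sets, or a microbial gap (a clamp spanning a host-specific insertion
   cannot bind the microbe at all — the strongest possible mismatch).
5. `rank_candidates()` orders candidates by the design objective:
   mismatches to the *closest* microbe, descending; then PNA Tm closest
   to the 80 °C design target; then fewest guideline breaches; then
   leftmost start, host strand first. The key tuple is a total order, so
   ranking is deterministic.

`design_blocking_primers()` reuses the same conservation machinery for
C3-spacer blockers: a seed oligomer (the overlapped primer's site for the
competitive strategy, the center of an internal conserved block for
elongation arrest) is extended base-by-base along the host consensus
until a target Tm — PCR-primer Tm plus 5 °C (short class) or 15 °C (long
class) — is met or conserved sequence runs out. By construction a long
design at a locus extends the short design at the same locus.

### The design guidelines, and why "soft" is the default

Candidate windows are screened against the published PNA design
guidelines: (i) Tm above the PCR primers, (ii) Tm above the extension
temperature, (iii) length 12–21 nt, (iv) no self-complementary
stretches, and (v) purine content below 50% with no purine run longer
than four. Experimentally validated clamps in the literature breach
single guidelines — a 24-nt ITS clamp, a clamp with a five-purine run,
a clamp at exactly 50% purines — so `design_constraints()` defaults to
`constraint_mode = "soft"`: every window is returned with its breaches
listed, and hard filtering is opt-in. The guideline screen is also
exposed directly:

```{r screen}
wheat_clamp_oligos() |>
  filter(kind == "pna") |>
  select(name, sequence) |>
  screen_clamp_guidelines() |>
  select(name, length, purine_fraction, max_purine_run, n_violations)
```

Guidelines (i) and (ii) involve two temperature notions (annealing vs.
melting) whose offset is instrument- and chemistry-dependent; the package
evaluates both as Tm predicates and reports margins rather than
collapsing them into one number.

### Mismatch aggregation

"Highest number of mismatches to microbial sequences" is ambiguous
between the minimum and the average over microbes. The package ranks by
the **minimum** (`mismatch_aggregate = "min"`), which matches the
at-least-five-SNPs safety reading: the microbe closest to the clamp is
the one at risk of off-target blocking. The mean is available as a
configuration switch.

## Melting temperatures

DNA/DNA duplex Tm (`tm_dna_nn()`) uses the unified nearest-neighbor
enthalpy/entropy table with terminal initiation penalties, an entropic
monovalent-salt correction (0.368·(N−1)·ln[Na+]), and the
oligo-concentration term (CT/4 for a non-self-complementary duplex).
Defaults: 50 mM monovalent salt, 250 nM oligo. Web calculators used in
practice are not reproducible offline and parity with any particular
vendor tool is not claimed; the NN model is validated in the test suite
against an independent implementation of the same published table to
within 0.1 °C.

PNA/DNA duplex Tm (`tm_pna()`) uses the published sequence-based linear
correlation

&nbsp;&nbsp;&nbsp;&nbsp;Tm(PNA) = c0 + c1·Tm(DNA) + c2·f~pyr~ + c3·n

with default coefficients (20.79, 0.83, −26.13, 0.44), where f~pyr~ is
the pyrimidine fraction of the PNA and n its length. For the
pyrimidine-rich oligomers that the purine guideline steers designs
toward, this predicts a PNA/DNA Tm above the DNA/DNA Tm, as PNA
chemistry requires. The coefficients are exposed in `thermo_config()`
because the vendor design tools they stand in for are black boxes.

Degenerate primers (e.g. `AACMGGATTAGATACCCKG`) are resolved to their
**most stable** concrete expansion by default (`degenerate_mode =
"max"`): for blocking purposes, annealing feasibility is governed by the
strongest variant. `"min"` and `"mean"` modes are available.

## In-silico PCR and blocking prediction

`find_primer_sites()` scans both strands with IUPAC-aware comparison.
Defaults: at most 2 total mismatches and **zero** mismatches in the
3'-terminal 5 nt — 3' mismatches are what abort extension, and this
stringency reproduces the practically important behaviour that some
primer pairs avoid host organellar templates on their own.
`predict_amplicons()` pairs every forward hit with every downstream
reverse hit (no shortest-product heuristic) and measures the product
from forward 5' end to reverse 5' end inclusive.

`predict_clamp_effect()` marks a product *blocked* when a clamp aligns
inside it (either strand, ungapped) with at most `block_max_mismatch`
mismatches. The default is 0: a single mismatch destabilizes PNA/DNA
hybrids enough to lose clamping in practice, which is also why a
five-mismatch design margin protects microbial templates.
`predict_composition()` is deliberately kinetics-free bookkeeping — each
template contributes its copy weight if any of its products escapes
every clamp. No PCR-efficiency or cycle simulation is attempted, because
the design decision it supports (which template classes survive
clamping) does not require kinetic claims.

## Mock-community normalization

`balanced_volumes()` and `unbalanced_volumes()` implement
genome-equivalent arithmetic: copies/µL = concentration / (genome length
× mass per bp) × marker copies per genome, with mass per bp defaulting
to 650 g·mol⁻¹ / N~A~ ≈ 1.0794×10⁻¹² ng. Volumes are chosen so each
member contributes equal (or target-profile) marker copies. This is a
reconstruction of the standard copy-number calculation from its stated
inputs; the package ships a 17-member **synthetic** bacterial panel
(`synthetic_mock_members()`) with typical genome sizes and 16S copy
numbers for exercising the math — it is a stand-in, not a measured
extract table. `compare_observed_expected()` reports per-taxon log2
ratios (pseudo-fraction 10⁻⁶ for zeros), the L1 distance between
profiles, and expected-but-undetected taxa. ITS copy numbers per genome
are poorly characterized for most fungi, so no fungal copy-number
database is attempted.

## The synthetic panel generator

`simulate_panel()` builds the study system every other module is tested
against: host rows that are identical across a planted clamp site,
microbial rows that each differ from that site by at least a requested
mismatch count, controlled per-site background divergence (defaults:
2% across host rows, 10% for microbes — typical intra-host reference
spread vs. inter-genus marker divergence), an embedded primer pair
(exactly one site per template, verified by re-scanning), and optionally
a host-specific insertion (default 320 bp) emitted as gap columns in the
microbial rows so the alignment is already columnized. The fixture is
its own oracle: every ground-truth claim is re-verifiable by
`build_profile()`, `score_candidates()`, and `predict_amplicons()`.

What it does **not** emulate: sequencing error, chimeras, length-biased
read merging, indel polymorphism outside the single insertion, or
phylogenetic correlation among microbes (sites are i.i.d.). Passing the
planted-site recovery tests therefore demonstrates that the search,
scoring, and ranking machinery is correct — not that real reference
panels are as clean as the fixture.

`simulate_labeled_counts()` draws host/taxon read counts from a seeded
multinomial for exercising the reporting arithmetic.

All generators take explicit integer seeds and restore the caller's RNG
state; no global random state leaks.

## Read-fraction reporting

`read_fraction_report()` computes the clamp-efficiency headline numbers:
microbial percentage per condition at full precision and rounded
half-away-from-zero to one decimal and to integer (the convention under
which 99.7785% prints as 99.8% and 66.75% as 67%). Taxonomic
classification of reads is out of scope — the module consumes
already-labeled counts, avoiding any bundled taxonomy pipeline.

```{r report}
wheat_clamp_read_counts() |>
  filter(assay == "16S_V5V7") |>
  read_fraction_report() |>
  select(condition, host_reads, microbial_reads, microbial_percent_1dp)
```

## Numerical and convention choices

* **Coordinates** are 1-based inclusive (`start`, `end`) everywhere, the
  native R convention; amplicon product length includes both primers.
* **Consensus ties** break in fixed base order A < C < G < T, then
  degenerate codes, then gap — deterministic across platforms.
* **Degenerate microbial bases** count as matches when their base set
  overlaps the clamp base: this understates divergence and never
  overstates clamp safety.
* **Windows with a degenerate host consensus** are skipped with a
  message — a PNA is synthesized as one concrete sequence.
* **Ranking** uses a total-order key tuple, so equal-mismatch candidates
  always emerge in the same order.
* Profile frequencies sum to 1 within 1e-9; mock recipes reproduce
  target fractions within 1e-9 relative tolerance.

## Validation scale

The shipped tests recover planted clamp sites across 20 seeded panels
with locus lengths from 60 to 800 columns (5 hosts, 8 microbes, ≥5
planted mismatches), and check the self-complementarity scan, primer
scanning, candidate enumeration, and report summaries against quadratic
brute-force re-implementations on 100 randomized instances each. These
sizes were chosen as the smallest panels that exercise every code path —
block boundaries, both strands, degenerate primers, gapped insertions —
while keeping the whole suite fast enough to run on every change.

## Known limitations

* No duplex-with-mismatch thermodynamics: mismatch counts are the
  divergence currency, not ΔΔG. Two clamps with equal mismatch counts
  but different mismatch identities are ranked equal.
* No parallel-orientation PNA binding; the canonical antiparallel mode
  is assumed.
* Exact reproduction of any published clamp sequence is not claimed:
  choosing among co-optimal candidates involves judgment (synthesis
  quirks, local secondary structure) that the ranking key does not
  encode.
* Clamp concentration/efficiency relationships (e.g. template dilution
  improving blocking) are not modeled; predictions are qualitative
  blocked/amplifiable calls at a configurable mismatch threshold.
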