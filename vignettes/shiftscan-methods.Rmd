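---
title: "Detecting -1 ribosomal frameshifting signals with shiftscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting -1 ribosomal frameshifting signals with shiftscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftscan)
```

## The biology in one page

Programmed −1 ribosomal frameshifting (PRF-1) fuses two overlapping
reading frames: at a defined signal the ribosome slips one nucleotide
backwards and continues in the −1 frame. The mandatory component is a
"slippery" motif — a tetramer `Z_ZZN` or a heptamer `X_XXZ_ZZN`, where
`XXX` and `ZZZ` are runs of identical bases and underscores mark the
frame-0 codon boundaries. On the heptamer, the P- and A-site tRNAs
(paired to `XXZ` and `ZZN`) can re-pair to `XXX` and `ZZZ` in the −1
frame. Frameshift frequency is raised by cis *stimulators*: an upstream
Shine–Dalgarno (SD)-like sequence that pairs with 16S rRNA inside an
elongating ribosome, and/or a downstream RNA structure (hairpin or
pseudoknot) that pauses the ribosome over the motif.

`shiftscan` implements the computational side of a systematic study of
these signals in enterobacterial coding sequences:

1. a census of all 64 heptamers (and 16 tetramers) in the three codon
   phases of a CDS collection;
2. a constrained-randomization null model and per-motif z-scores that
   quantify under-representation;
3. candidate-gene discovery by clustering, motif-conservation filtering
   and stimulator detection with empirical energetic rules;
4. a reporter-assay analysis that converts β-galactosidase activities
   into frameshift percentages and classifies motifs as
   frameshift-prone;
5. seed-deterministic synthetic-data generators so every stage can be
   exercised end-to-end without any external download.

## Phase conventions

All coordinates in the package are 0-based with half-open intervals.
The *phase* of a motif occurrence is `start %% 3` within its CDS.
Writing the codon layout out:

```
codon:   ... | a  a  X | X  X  Z | Z  Z  N | ...
offset:        .  .  s  .  .  .  .  .  .
```

the in-frame "shifty" configuration `X_XXZ_ZZN` places the motif's
first base on the last position of a codon, i.e. `start %% 3 == 2`.
The two out-of-frame readings of the same 7-mer are phases 1 and 0.
CDS scans include the terminal stop codon, which is part of the coding
sequence as distributed in standard CDS FASTA exports.

```{r phases}
scan_motifs("ATGGCAAAAAAGTAA", enumerate_heptamers())
```

All overlapping occurrences are counted (a poly-A run of length L
contains L − 6 heptamer occurrences); this is the simplest reproducible
convention and the one the zero-filled 64 × 3 frequency table assumes.

## The null model

To ask whether a motif is avoided *because it is slippery*, its count
must be compared against genomes that share every confounding property
except motif-level selection. `dicodon_shuffle()` randomizes each gene
under three **exact** invariants: the encoded protein, the codon
multiset (codon usage), and all 16 dinucleotide counts of the full
sequence. The sampler is a Markov chain of codon swaps between
positions encoding the same amino acid; a proposed swap is accepted
only when the multiset of junction dinucleotides it touches is
unchanged (codon-internal dinucleotides travel with their codons).
This acceptance test is exact rather than a sufficient condition, so
every output satisfies the invariants to zero tolerance — the
acceptance suite verifies this for 1000 random sequences. The first
codon is held fixed (start-codon integrity) and the stop codon is part
of the shuffled region.

Two practical notes on this design:

* *Mixing.* Junction-preserving synonymous swaps are rare events, so
  the chain (default `10 × n_codons` attempted swaps) explores a
  constrained neighbourhood rather than sampling the admissible set
  uniformly. On genomes drawn from the generator the resulting
  z-scores are nevertheless well calibrated — the acceptance suite
  checks that the mean z over the 64 shifty-phase cells lies within
  ±0.15 at 2000 genes × 500 replicates — which is the property the
  statistic needs.
* *Determinism.* Replicate `r` of `randomize_genome()` /
  `null_frequency_summary()` is reproducible from `(seed, r)` alone;
  null moments are streamed so 500–1000 replicate genomes are never
  held in memory.

The z-score for a (pattern, phase) cell is
`z = (x − x_mean) / x_sd`, with the moments taken over the replicate
counts; negative z means under-representation. Cells with zero null
variance are flagged undefined and excluded from correlations, which
use Pearson's r with a two-sided t-test on n − 2 degrees of freedom
(the source analysis reports P without naming a test; the t-test is
the standard choice for Pearson correlations of this size).

Candidate motifs are selected by the rule `z < 0` in the shifty phase
AND in-vivo efficiency `> 0.10%` without stimulators, plus a manual
set of high-efficiency additions; with published-style inputs this
yields 18 + 3 = 21 patterns.

## Candidate-gene filtering

Genes carrying a selected motif are grouped with
`greedy_cluster()` — greedy incremental clustering against cluster
representatives under global-alignment identity (matches / alignment
columns), used at 0.95 on nucleotides for redundancy removal and 0.45
on proteins for family building. It is deterministic given the input
order and always yields a partition. Protein alignments (built-in star
alignment around the longest member, or any externally produced MSA)
are back-translated codon-wise so that gaps never split codons, and
the conserved motif coordinate is mapped through each member's gaps.

`tally_conservation()` classifies each member, in priority order:

* `N1` — the exact parent heptamer at the conserved column;
* `N2` — any of the 64 heptamers at that column;
* `N3` — any heptamer within a 36-nt window starting 15 nt upstream of
  the mapped site (ungapped member coordinates, truncated at the
  ends); members with a gap at the site fall into this category check.

The priority order makes the categories mutually exclusive so that
`N_sum = N1 + N2 + N3 ≤ N_all` and the conservation rule
`N_sum / N_all > 0.9` (strict) is well defined; eligibility also
requires at least 20 members. The boundary — ratio exactly 0.9 is not
conserved — is locked by tests. Screens for the motif are run in the
shifty phase of the annotated frame; this phase filter is the
biological intent of the overlap definition even though a
frame-agnostic screen is possible (it can be emulated by scanning all
phases with `scan_motifs()`).

## Stimulator detection

**SD-like elements.** The 30-nt segment ending at (and excluding) the
motif's first base is scanned for GAGG, GGAG, AGGA, GGNGG and AGGKG
(K = T/G), the patterns with experimentally demonstrated stimulatory
activity. A hit is retained when its spacing is 6–17 nt. The spacing
anchor had to be frozen: the package counts the nucleotides strictly
between the last base of the SD match and the second base of the
motif, plus one — so an SD followed by 9 spacer nt before the motif
has spacing 10. A cluster has a "conserved SD" when at least 50% of
its members have a retained hit (inclusive).

**Hairpins.** A downstream segment of up to 197 nt starting at the
fourth base after the motif is extracted; every 3′ truncation from the
full length down to 17 nt is folded by the engine, and each fold's
outermost structure element (first paired base to its partner) becomes
a candidate. Retention rules, all inclusive:

| rule | bound |
|------|-------|
| length (first to last paired base) | 17–140 nt |
| distance from motif's last base | 4–10 nt |
| closing stem | G-C (or C-G) outermost pair + ≥ 3 consecutive WC/G·U pairs |
| ΔG~unfold~ | ≥ 7.6 kcal/mol |

ΔG~unfold~ is defined as the negation of the engine's folding free
energy at 37 °C (positive for stable folds), and ΔG~hp~·nt⁻¹ divides
it by the structure length (loops and bulges included). Identical
(structure, length, distance) triples arising from nested truncations
are deduplicated. Structure *types* group candidates by exact
(length, distance); types present in ≥ 50% of members survive, and the
best type maximizes ΔG~hp~·nt⁻¹ × frequency (ties: larger
ΔG~hp~·nt⁻¹, then smaller distance).

The enrichment statistic slides a window of the conserved hairpin's
size along the 197-nt segment (step 1 nt), folds each window, and
computes ΔΔG·nt⁻¹ = ΔG~hp~·nt⁻¹ − mean(ΔG~unfold~·nt⁻¹ over windows).
Values ≥ 0.09 kcal/mol/nt mark IS-element-like structural enrichment
— selection maintaining a hairpin should make it more structured than
its neighbourhood.

**Folding engines.** Folding goes through a pluggable contract:
`vienna_engine()` shells out to the RNAfold program (default Turner
parameters, 37 °C), and `stub_engine()` replays a fixture table of
precomputed structures/energies so that every rule boundary can be
unit-tested deterministically, independent of folding-engine versions.
Pseudoknots are out of scope (the MFE structures used here are
nested); when a fold contains several disjoint stems only the
earliest-starting element is considered.

## Reporter-assay analysis

Frameshift frequency is the mean over replicates of
100 × activity / mean(in-frame reference activity); it is invariant to
rescaling all activities by a common factor. The efficiency classifier
divides a motif's percentage by its non-shifty control's percentage
(per-motif controls where assayed; a context-wide scalar background —
0.069% for the strong-pseudoknot context — where not) and calls the
motif frameshift-prone when the ratio exceeds 2, strictly. Mean of
per-replicate ratios is used rather than ratio of means; at the
replicate CVs of such assays the difference is far below the
classification margins.

Non-shifty controls keep the A-site tRNA (tetramers) or both the P-
and A-site tRNAs (heptamers): only the first base (tetramer), or the
first and fourth (heptamer), are mutated. The package resolves the
eight heptamer control templates by the rule *base 1 → C if X is a
purine else G; base 4 → the transition partner of Z* — a
third-position transition in the P-site codon, read by the same tRNA.

## The synthetic-data generators

Every consuming module is fed by a generator whose defaults are the
study conditions:

* `gen_genome()` — 2000 genes, gamma-distributed lengths with mean 250
  codons (minimum 60), E. coli K-12 codon usage, ATG starts and
  usage-weighted stops. An optional junction-dinucleotide bias
  (rejection reweighting toward a CpG/TpA-shifted target) gives the
  shuffler a non-trivial dinucleotide structure to preserve; it is off
  by default so that calibration runs are i.i.d.-codon draws from the
  null.
* `deplete_pattern()` — removes a chosen fraction of a motif's
  shifty-phase occurrences by synonymous codon replacement, leaving
  every protein untouched; used to plant an under-representation
  signal. The recovery checks use `AAAAAAA`, whose Lys-Lys codon path
  makes it frequent enough (on the order of 100 shifty-phase
  occurrences at the default scale) for a 50% depletion to be
  recovered unambiguously at z < −3.
* `gen_cluster()` — a parent CDS with the motif planted in the shifty
  phase (an alanine codon supplies the X base, so no stop can arise),
  members derived by per-site substitution with the motif window
  optionally masked, and optional whole-codon jitter that moves the
  motif into the 36-nt window category. Member labels are computed by
  direct inspection and cross-checked against `tally_conservation()`.
* `plant_stimulators()` — overwrites a designed upstream segment with
  an SD match at a requested spacing and a GC-rich inverted repeat
  forming a stem-loop at a requested distance; length and reading
  frame are preserved (substitution only).
* `gen_assay_table()` — long-format replicate tables from a truth
  table, log-normal multiplicative noise with chosen CV (5 replicates,
  CV 5% by default); CV 0 recovers the truth exactly.
* `synthetic_assay_truth()` / `synthetic_zscore_table()` — synthetic
  counterparts of the per-motif summary tables. Only their *marginal
  structure* is planted (which motifs are prone per context: 39, 55
  and 61 of 64, with the three named pseudoknot non-responders; which
  18 patterns satisfy the selection rule; which three are manual
  additions); per-motif magnitudes are spread over realistic ranges
  following a mechanistic shiftiness ranking (A/U-starting A-site
  codons, homogeneous ZZN, homogeneous X/Z, AAG lysine slippage), with
  margins wide enough that the 5-replicate, 5%-CV classifier recovers
  the planted sets deterministically.

What passing on these data does and does not show: the generators
produce equal-length, indel-free clusters, i.i.d.-codon genes, and
noise that is homoscedastic on the log scale. Real CDS collections
have length-correlated composition, indels, phylogenetic structure and
context-dependent assay noise; results on synthetic data validate the
machinery (coordinates, invariants, thresholds, statistics), not the
biological conclusions one would draw from real genomes.

## Numerical and design choices

* All rule thresholds are implemented with the stated strictness
  (ratio > 2 strict, N_sum/N_all > 0.9 strict, frequency ≥ 0.5
  inclusive, ΔG ≥ 7.6 inclusive, ΔΔG ≥ 0.09 inclusive) and each edge
  is pinned by a boundary fixture in the test suite.
* Null standard deviations use the n − 1 sample convention; at 500–
  1000 replicates the difference from the population convention is
  negligible.
* Sequences with no admissible rearrangement shuffle to themselves;
  genes shorter than three codons cannot move at all.
* `greedy_cluster` identity includes terminal gaps in the column count,
  making identity symmetric in sequence length.
* Degenerate inputs: empty genomes, missing pattern rows, zero-variance
  correlations, frameshifted alignment rows and unbalanced dot-bracket
  strings raise informative errors rather than propagating NA.
* Problem sizes in the acceptance suite — 2000 genes × 500 replicates
  for calibration and depletion, 1000 sequences for shuffle exactness,
  500 random instances per scanner oracle, 20-member clusters for the
  folding round trip — are the package's chosen study scale; the
  genome-scale analyses the method targets (tens of thousands of genes,
  1000 randomizations) use the same code paths with larger `n`.

## Known limitations

* The shuffler documents no uniformity guarantee over the admissible
  set; it is an exact-invariant sampler, not an exact-uniform one.
* The conservation statistic (`syn_conservation_profile`) is a
  homogeneous-rate binomial window test and `aln_div` a star-phylogeny
  approximation; both ignore shared ancestry and are meant as
  desk-scale flags, not substitutes for phylogenetic methods.
* Pseudoknots are not modelled; hairpin detection sees only nested MFE
  structures.
* The built-in star aligner is adequate for the generator's indel-free
  clusters and mildly gapped inputs; heavily diverged families should
  be aligned with a dedicated MSA tool and imported.
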