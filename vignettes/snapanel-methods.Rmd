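---
title: "Designing and decoding multiplex SNaPshot minisequencing panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and decoding multiplex SNaPshot minisequencing panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapanel)
```

## The assay model

A SNaPshot minisequencing panel reads `n` biallelic SNVs in one capillary
lane. For each SNV an extension primer anneals with its 3′ terminus on the
base immediately adjacent to the polymorphic position; a single fluorescent
ddNTP is incorporated, so the product is exactly `total primer length + 1`
nt and its dye channel encodes the incorporated base (A green, C black,
G blue, T red in the ABI chemistry). The decoding rule is: a heterozygote
shows two peaks of the same size and different colour, a homozygote one
peak; across the panel a noise-free electropherogram therefore carries
between `n` and `2n` peaks, and a panel of `n` SNVs spans `n` heterozygous
and `2n` homozygous genotype classes.

Primer-sense bookkeeping is the one genuinely error-prone part of the
model. A primer may read either strand; the incorporated base for an allele
is that allele *as read on the primer-sense strand* (complemented for a
minus-strand primer), and that base — not the genomic allele — selects the
dye. `detected_bases()` is the single source of truth for this algebra, and
every genotype the package reports is converted back to the genome plus
strand. We fixed this convention package-wide because the published panel
tables we transcribe mix genome- and gene-relative direction labels; the
printed direction letters are retained as metadata but play no role in any
computation. For the packaged panels each primer's strand is inferred by
order-sensitively matching the printed detected-allele pair against
(ref, alt) and its complement; all 28 rows resolve unambiguously, and the
result (all 12-plex primers on the genome minus strand, consistent with the
gene's minus-strand orientation; all 16-plex primers on plus) is also the
biochemically coherent reading.

## Design constraints and their defaults

All numeric rules live in one `design_constraints()` object:

* **Tm window 57–64 °C, PCR primer length 17–29 nt** — the published
  assay's windows. The original Tm values came from a web calculator whose
  formula is not stated, so the exact window cannot be reproduced
  bit-for-bit; we default to the unified nearest-neighbour model
  (dinucleotide enthalpies/entropies, terminal initiation terms, entropy
  salt correction `0.368 (N−1) ln[Na+]` at 50 mM Na+, `CT/4` symmetry
  factor at 250 nM total oligo), with the Wallace rule (`2AT + 4GC`) as a
  closed-form cheap mode. Because the published formula is unknown, Tm
  window checks are always *report-only* warnings, never errors.
* **`same_dye_min_gap` = 4 nt, `empirical_min_gap` = 3 nt** — two products
  that can share a dye channel must differ in nominal size by at least
  4 nt; 3 nt is the empirical floor below which neighbouring same-dye peaks
  stop resolving. The designer enforces 4; the checker treats sub-4-nt gaps
  as errors for newly designed panels and as warnings for imported ones,
  because the published 16-plex itself contains nominally coincident
  same-dye 32-mers that the instrument separated through sequence- and
  dye-dependent mobility. (One fixture note: of the two published
  thresholds, we attach the hard error to the 4-nt design rule rather than
  the 3-nt empirical floor; the floor is annotated inside the message.)
* **`readable_window` = [15, 120] nt** — the span of the GeneScan-120 LIZ
  size standard; every extension product (primer + 1) must sit inside it.
* **Neutral master tail** — the 40-mer
  `aactgactaaactaggtgccacgtcgtgaaagtctgacaa`. Tails of length `k ≤ 40` are
  its length-`k` suffix; longer tails prepend poly(C). The master is the
  common suffix evident across the published primer set (26 of 28 printed
  tails are exact suffixes; two start `tcagg` instead of the master's
  `ctagg`, a transposition we treat as data and flag in tests, not as a
  rule). The suffix construction keeps tails non-genomic and reproducible.
* **Screening thresholds `hairpin_max_stem` = 7, `dimer_max_run3` = 7** —
  the hairpin and dimer screens are exact combinatorial run-finders (longest
  self-complementary stem with a ≥ 3 nt loop; longest Watson–Crick
  complementary run over all ungapped antiparallel alignments, plus the
  longest such run touching either 3′ terminus), not free-energy folds.
  Thresholds were calibrated against the published primers: that set
  contains a 6-bp stem and a 6-bp 3′-anchored self-run that evidently
  performed well, so the flag level is 7.

## The length-staggering solver

`solve_spacing()` assigns each primer a total length ≥ its genomic core
length such that (a) primers sharing ≥ 1 dye differ by ≥ 4 nt, (b) every
product fits the readable window, (c) the maximum total length is minimal,
and (d) among minimal-makespan solutions the lexicographically smallest
assignment in input order is returned — (d) makes the whole designer
deterministic without any seed. The conflict graph is the union of four dye
cliques, solved per connected component: a clique lower bound
(`min core + (m−1)·gap`) seeds the makespan search, feasibility at each
candidate makespan is decided by depth-first search with forward checking,
and a second pass re-runs the lexicographic search with every component
capped at the global minimal makespan (a component may "borrow" slack from
the critical one, which matters for lexicographic minimality). On instances
of ≤ 4 primers the solver provably matches exhaustive search (tested); a
16-primer panel solves in seconds.

The spacing constraint is enforced on *nominal* sizes. Observed sizes
diverge from nominal through dye mass and polymer effects (strongest below
~50 nt); `mobility_model()` carries per-dye affine corrections
(`observed = offset + slope · nominal`, identity by default) and
`fit_mobility()` estimates them from control runs by per-dye least squares
(offset-only when a dye has a single observation; identity with a warning
when it has none). No published mobility offsets exist to ship as defaults
— the divergences are described but not tabulated — which is why the model
defaults to the identity and is fitted per instrument.

## Decoding parameters

`call_genotypes()` matches peaks to expected (dye, size) slots within
`size_tol` (default 1.0 nt) and calls a heterozygote only when the
minor/major peak-height ratio reaches `het_ratio_min` (default 0.15). The
source assay reports neither value; these defaults were chosen so that the
noise model below decodes comfortably and both are exposed. The height
filter is what keeps low non-specific peaks (simulated at 3–8 % of the
nominal height) from flipping homozygotes to heterozygotes; unassignable
peaks are flagged and retained, never silently dropped, and two same-dye
peaks inside one allele window flag the call as ambiguous rather than
raising an error.

## What the generators emulate — and what they do not

Two synthetic inputs make the package testable end-to-end without any
download:

* `build_toy_genome()` embeds, for each published PCR row, a pseudo-amplicon
  (real forward primer + seeded random filler + reverse complement of the
  real reverse primer, at the printed amplicon length) in random background.
  In-silico PCR on it reproduces all 22 printed amplicon lengths *by
  construction of the interval, not of the interior*: the amplicon interiors
  are synthetic because the reference genome is not packaged, so
  extension-primer cores for the fixture panels come from the published
  table verbatim rather than being re-derived.
* `simulate_locus()` generates a uniform-random window with evenly spread
  SNVs for designer tests.
* `simulate_peaks()` draws Gaussian sizing jitter (the acceptance noise
  condition is sd = `size_tol`/3 with two uniform non-specific peaks per
  run, under which decoding concordance stays ≥ 99 %; noise-free decoding
  is exact, mirroring the assay's 100 % validation against sequencing and
  RFLP).

None of these reproduce real-data pathologies: pull-up between dye
channels, heteroduplex stutter, allele-specific extension efficiency,
primer batch effects, or sequence-dependent mobility beyond the affine
per-dye model. Passing tests therefore demonstrate the correctness of the
design and decoding logic under the stated model, not instrument-level
robustness.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout; half-open arithmetic exists
  only inside sequence slicing. Sequences are upper-cased internally; tails
  serialize lower-case.
* In-silico PCR and the uniqueness scan are exact string matches (both
  orientations; a palindromic primer present once counts twice). This is a
  deliberate network-free stand-in for a BLAST homology screen and will not
  find mismatched binding sites.
* Restriction digestion cuts at the 5′ end of each IUPAC match by default
  (`cut_offset` configurable); overlapping matches are all counted, and
  non-palindromic patterns are additionally scanned in reverse-complement
  orientation. Fragment boundary conventions affect fragment sizes but not
  the informative/uninformative verdict, which is the quantity the RFLP
  check uses.
* Reaction partitioning is greedy colouring by descending conflict degree
  (ties in input order) — deterministic, and within one colour of the exact
  chromatic number on the random graphs we test. The published A/B split is
  carried as data; no algorithm for it was published.
* Targets must be biallelic SNVs; multi-allelic or indel targets are
  rejected at construction. A target whose both strands are blocked by
  flanking variants (the footprint includes the interrogated base, so an
  indel overlapping the SNP blocks both strands) is reported undesignable
  and excluded without failing the rest of the panel — the same reasoning
  that excluded rs7775698 from the published 16-plex.

## Problem sizes used by the test-suite

Unit tests run on windows of 0.4–8 kb with 1–12 synthetic SNVs; the
round-trip suite decodes 1,000 simulated 12-plex runs under the acceptance
noise model; digestion conservation is checked on 1,000 random
amplicon/pattern draws; the spacing solver is cross-checked against
exhaustive search on dozens of ≤ 4-primer instances over a reduced
15–40 nt window (chosen so exhaustive enumeration stays exact and cheap);
greedy colouring is compared with the exact chromatic number on 100 random
6-node graphs. The whole suite completes in a couple of minutes on one CPU.

## Known limitations

* Tm estimates will not match the unpublished calculator the original
  design used; the 57–64 °C window is reported, never enforced as an error.
* The homology screen is exact-match only (pluggable: any FASTA can be
  supplied, and a real BLAST can replace it upstream).
* One extension reaction per panel is assumed (as in the source assays);
  automatic splitting of extension multiplexes and concentration balancing
  are out of scope — concentrations are carried as metadata.
* The mobility model is affine per dye; strongly non-linear sub-50-nt
  behaviour is only approximated.
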