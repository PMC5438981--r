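---
title: "Plastome architecture, rps16 decay and repeat-origin scenarios: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome architecture, rps16 decay and repeat-origin scenarios: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastrep)
```

This vignette documents the models, conventions and numerical choices
behind `plastrep`, in the order the pipeline applies them. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Coordinates and the quadripartite model

All coordinates are 0-based, half-open, on the record's deposited
linearization; circularity is explicit (`is_circular`), never inferred,
and wrap-around intervals carry a `wraps` flag. This makes interval
arithmetic across the origin unambiguous: the length of a wrapping
interval is `(end - start) mod n`.

The quadripartite model is the standard one: two identical inverted
repeat arms (IRa is the exact reverse complement of IRb) separating a
long and a short single-copy arc. `find_inverted_repeat()` searches for
the maximal pair of disjoint intervals whose sequences are reverse
complements:

* **Algorithm.** k-mer seeding (k = 25) between the sequence and its
  reverse complement; seeds sharing an anti-diagonal offset are grouped,
  and each candidate offset is scanned with a single vectorized base
  comparison whose maximal `TRUE` runs are the exact matches. With a 25 nt
  seed, chance seed collisions on a 160 kb genome are vanishingly rare, so
  only genuine repeats generate candidate offsets.
* **Exactness.** The default `max_mismatch_frac = 0` reflects that
  plastome IR arms are near-identical in practice and makes maximality
  testable: extending either boundary by one base breaks the identity.
  A tolerant mode merges neighbouring exact runs while the merged span
  stays within the mismatch budget.
* **Tie-break.** Among equal-length candidates the pair minimizing the
  LSC start coordinate wins, so detection is deterministic.
* **Limitation.** Detection operates on the linearized sequence; an arm
  split by the chosen origin is not rejoined. Deposited plastomes
  conventionally start in the LSC, and the synthetic generator follows
  that convention.

`partition()` assigns the longer gap arc to the LSC and labels the arm
that follows the LSC in circular order IRb, so the circle always reads
LSC–IRb–SSC–IRa. Lineages that have lost one IR raise a no-IR error
rather than a degenerate partition; the caller decides how to proceed.

## Junction contexts

Each junction's reference point is the *first base of the IR arm* crossed
when walking from single-copy sequence into the repeat (for JLB that is
the first base of IRb; for JSB, walking backwards from the SSC, the last
base of IRb, and so on). A gene *contains* the junction when the point
falls inside its half-open span; the reported `overlap_bp` counts the
gene's bases on the IR side of the point, matching the "expanded x bp
into gene" phrasing of junction surveys. Two consequences of the
half-open convention worth noting: a junction point on a gene's first
base counts the whole gene as duplicated, while a gene ending exactly at
the point yields an intergenic context. Intergenic contexts are labelled
`"<IR-side gene>/<single-copy-side gene>"` from the nearest annotated
genes within a 5 kb window (default); with no annotation in reach the
context is `"unresolved"`, never an exception.

## rps16 integrity typing

The locus decays through five observable states: `INTACT`, `EXON1_LOST`,
`EXON2_LOST`, `EXON2_PARTIAL` (a short exon-2 remnant), and
`COMPLETE_LOSS`. Each reference exon is sought by affine-gap local
alignment (match 1 / mismatch −1 / gap open −2 / extend −1, both
strands). Because a Smith–Waterman optimum may append a lucky
low-identity extension into flanking sequence, the retained length is
measured on the alignment trimmed to its maximal-scoring core under a
stricter +1/−3 column score; this keeps a planted 47 bp remnant measured
at 47 bp and prevents random sequence from spuriously "anchoring" an
absent exon. Thresholds, exposed as arguments:

* `anchor_bp = 20` — minimum aligned reference bases to consider an exon
  present at all;
* `full_frac = 0.9` — fraction of the reference required to call an exon
  full length;
* `min_identity = 0.8` — minimum identity of the trimmed core.

The survey literature gives only the endpoint states, so these two
thresholds are this package's choices to make the spectrum decidable;
they sit far from both the full-length and the absent regimes and the
test suite exercises all five states with them.

The in-silico PCR used for the *Veratrum* section marker requires, per
primer, at most `max_mismatch` mismatches (default 0) with an exact
3'-terminal base, the two footprints disjoint on opposite strands, and a
product ≤ 3 kb sized inclusive of both primers. Circular templates are
scanned across the origin by extending the sequence by one maximal
product length. The section rule is purely size-based — one product of
1200–1800 bp calls sect. Veratrum, one of 300–500 bp calls sect.
Fuscoveratrum, anything else is indeterminate — so it can be applied to
gel sizes as well as in-silico products.

## Spacer profiling

`extract_igs()` profiles the rpl23–ycf2 cassette copy on the strand where
rpl23 immediately precedes ycf2 5'→3' (the mirror copy in the other IR
arm is its reverse complement and is skipped to avoid double counting).
trnI_CAU copies are counted by ungapped similarity to a reference tRNA
(≥ 95% identity over the full reference, truncated terminal copies
accepted at ≥ 95% coverage) rather than by annotation, so under-annotated
records still count their duplicates. Sub-spacer lengths follow the
survey convention: rpl23→first trnI and last trnI→ycf2; with no internal
trnI the whole spacer is reported on the rpl23 side.

`find_tandem_repeats()` reports maximal tandem tracts for periods 18–250
bp. The identity contract is per-copy Hamming identity against the
*first* copy (the consensus), with tolerance `max_mismatch_frac = 0.1`; a
partial trailing copy is reported as `tail_bp`, never as an extra unit.
Overlapping candidate reports are collapsed to one tract per segment by
the ordering: most copies, then highest mean copy identity, then smaller
period, then smaller start. The identity criterion is load-bearing: with
mismatch tolerance, a one-to-few-base shift of an exact tract is also a
valid candidate with the same copy count, and a start-position tie-break
alone would report the shifted variant. The detector is validated against
an independent O(n³) enumeration of all (start, period, run) triples on
hundreds of seeded sequences. "Total repeat units" is the sum of integer
copy counts over arrays with unit length ≥ 18 bp, matching the unit-count
column of comparative spacer tables; the 18 bp floor and all bounds are
config-exposed because the repeat-finder settings behind published tables
are usually unstated.

Motif scanning is exact substring search over the five-motif catalog
(`motif_catalog()`), reporting all, including overlapping, occurrences —
a U16 hit therefore always co-occurs with a D7 hit at the same position,
and R1/R1a hits imply internal R1b hits.

## The scenario decision table

Published repeat-origin narratives are prose; `classify_scenario()`
formalizes them as six ordered, first-match rules (see the README table)
so the inference is reproducible and falsifiable. Decisions taken where
the narrative is open:

* Rule 2 accepts ≥ 3 trnI copies rather than exactly 3, tolerating
  over-expanded arrays (threshold exposed).
* Rule 4 requires the R1a motif to be *observed* in sequence, not merely
  inferred from a postulated point mutation; the evidence list records
  this.
* Survey rows annotated with unprinted footnote marks are exempt from
  validation and route to `COMPLEX` or match opportunistically — the
  package does not guess an unprinted legend.
* `NONE` if and only if no qualifying array exists (tested as a
  bi-implication).

`survey_row_profile()` reconstructs minimal profiles from the published
68-taxon survey table plus the narrative's structural facts (multi-trnI
repeats span the tRNA; U16 marks the HFIR pathway; R1a marks the
point-mutation pathway; single-trnI repeats sit downstream of trnI). The
decision table reproduces the printed call for all 56 unflagged rows;
this is a consistency check of the formalization against its source, not
an independent measurement.

## The synthetic generator

`generate_plastome()` plants every structure the pipeline later measures;
defaults are the family-typical study conditions: LSC 85 kb, SSC 18 kb,
IR 27 kb, background GC 37.5% (planted as exact base counts, not
expectations, so composition tests exercise the rounding path), JLB 6 bp
inside rps3, intact rps16, repeat-free spacer. Junction cassette order
along the chromosome is rps3–rpl22–rps19–trnH_GUG with the tRNA deepest
in the IR. Three construction details matter for exactness:

* **Extension blocking.** The single-copy bases adjacent to the IR arms
  are set so they cannot pair under reverse complementation; otherwise a
  planted arm would extend by one lucky base in ~25% of seeds and
  coordinate-exact recovery would be impossible by construction.
* **Tract guards.** The bases flanking a planted tandem tract are forced
  to differ from the unit continuation, making the planted tract the
  unique maximal report.
* **Remnant guard.** The base preceding the planted 47 bp exon-2 remnant
  differs from the reference continuation, so retention measures exactly
  47.

`simulate_ssm_cassette()` is generative only: scenario I duplicates an
R1b-anchored window spanning the whole trnI to three copies; II applies
the single A→C mutation that turns the trnI-proximal R1 into R1a, then
one duplication; III_A inserts a fresh ~30 bp unit downstream of trnI and
expands it; III_B fuses the two D7 copies into U16 and expands a window
containing both U16 and trnI. Every event is appended to an event log
that classifiers never read. Gene sequences are fixed internal constants
of this package (synthetic, versioned); the motif and primer strings are
the published ones.

`mutate()` applies i.i.d. substitutions at a configurable rate;
`generate_plastome()` restricts mutation to background sequence with
50 bp margins at region boundaries and re-mirrors IRb onto IRa afterwards,
so planted coordinates and the IR identity survive mutation. Rates are
capped at 5%.

What the generator does not emulate — and hence what passing tests do not
show about real data: annotation errors and dialect quirks beyond tRNA
naming, indels and rearrangements outside the scripted events, IR-lacking
genomes, heteroplasmy, and repeat tracts whose copies diverged beyond the
10% tolerance. Real-accession behaviour should be checked by running
`run_pipeline()` on downloaded GenBank records.

## Problem sizes and determinism

The test suite and acceptance script size their panels as: 200 sequences
(≤ 500 nt) for the tandem brute-force comparison, 50 templates (≤ 10 kb)
for the PCR oracle, 100 cassette recoveries (5 scenarios × 20 seeds), and
50 planted genomes — mostly compact (~12–16 kb) with a handful at full
plastome scale, which exercises the identical code path at realistic
coordinates. All randomness is seeded; identical configurations produce
byte-identical genomes, and every RNG use is wrapped so callers' RNG
state is left untouched.

## Known limitations

* IR arms split by the linearization origin are not rejoined.
* Junction overlap uses the gene's outer span; a junction falling in the
  intron of a multi-exon gene still reports that gene.
* The tolerant IR mode (mismatch merging) is greedy, not optimal.
* `length_spectrum()` tallies units by array unit length; it does not
  re-measure divergence within arrays.
* The scenario table is a formalization of qualitative hypotheses; its
  calls are only as good as the motif/copy-number evidence it consumes.
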