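---
title: "svforge: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svforge: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

svforge simulates structural variants (SVs) on a reference genome and
produces a synthetic diploid genome together with an exact truthset. This
vignette explains the model, the choices made where the design was open,
and what the test suite does and does not demonstrate.

## The simulation model

A simulation is a set of SV *categories*, each the 4-tuple
**(t, D, C, n)**:

* **t** — the SV type, either one of the 26 predefined classes or a custom
  rearrangement expression;
* **D** — breakend distance ranges: for every length-bearing symbol of the
  rule (source letters, dispersions, novel insertion letters) either an
  integer range `[min, max]` in bp, sampled uniformly, or a derivation
  `"k*length(X)"` evaluated after `X` is sampled (rounded to the nearest
  integer, floor 1 bp);
* **C** — optional placement constraints against labeled ROI tracks;
* **n** — the number of events to draw.

Generation proceeds in three stages: (1) instantiate the *n* events by
sampling lengths and assigning zygosity (homozygous with probability
`homozygous_prob`, default 0.5; heterozygous events land on one haplotype
chosen uniformly; homozygous events occupy identical coordinates on both
haplotypes); (2) choose reference coordinates for every event subject to
the constraints, non-overlap and the minimum inter-SV distance; (3) edit
the reference into the two output haplotypes and emit the truthset.

Categories can also be a VCF of pre-specified SVs (`vcf:` key). Those are
incorporated verbatim at their recorded coordinates, bypassing random
placement (they are still booked into the occupied index, and a conflict
with the placement rules is an error).

## Grammar semantics

A rule `SRC→TGT` rewrites an ordered run of reference intervals. Source
letters are distinct capitals; `_` is a dispersion interval that separates
*segments*; target letters may repeat (copies), appear lowercase
(inverted), carry a `+` (copy count drawn from the category's
`copy_number` range), or be absent from the source (novel insertion,
random sequence or sampled from a user FASTA). `()` on the source side
marks the anchored sub-span bound by placement constraints; empty `()`
anchors a single breakend.

Deriving edit operations requires deciding which target occurrence of a
letter is the *in-place* one. svforge matches, within each segment, the
source letters against the target tokens with a longest-common-subsequence
alignment that prefers the earliest target occurrences. Matched tokens are
`IDENTITY`/`INVERT_IN_PLACE`; unmatched extra occurrences adjacent to the
in-place run are `TANDEM_COPY`, other extras `DISPERSED_COPY`; a letter
whose sole occurrence moved is `CUT_PASTE`; letters missing from the target
are `DELETE`; target-only letters are `NOVEL_INSERT`. This reproduces the
conventional readings: `ABC→ACB` keeps A and C in place and moves B;
`ABC→AABCC` is a tandem duplication of A and C.

The registry completes the predefined catalog to exactly 26 entries by
adding the symmetric counterparts of the asymmetric classes (e.g. both
`A→Aa` and `A→aA` inverted duplications) alongside the simple classes,
dispersion-based classes, flanked inversions, reciprocal translocations
(intra- and inter-chromosomal), SNPs and tandem-repeat
expansions/contractions. The roster and its names are a design choice of
this package; any other rearrangement is available through the grammar.

## Placement

Placement is greedy, most-restrictive-first: VCF-fixed SVs, then `exact`,
`partial`, `containing`, `contained`, then `terminal`/`whole_chromosome`,
then unconstrained and blacklist-only categories; ties are broken by
descending total span and then stable input order. The slotting of
`terminal`/`whole_chromosome` (just before unconstrained) and of
blacklist-only categories (with unconstrained) is our choice, as is
measuring the minimum inter-SV distance breakend-to-breakend.

For ROI-bound modes the sampler enumerates admissible ROIs and samples
positions within them directly, which terminates even when the feasible
set is small; unconstrained and blacklist modes sample genome-wide with
rejection. Every proposal is audited against chromosome bounds, the
per-haplotype occupied-interval index, the breakend distance floor and all
blacklists; lengths are redrawn on every attempt, and after
`max_placement_attempts` rejections (default 100) placement fails with an
error naming the SV, its category and the binding constraint. `exact` mode
additionally performs an early feasibility check (no ROI width inside the
anchored length range is diagnosed before any sampling) and overrides the
sampled anchored lengths to the chosen ROI's width, preserving their
proportions.

Mode semantics, on the anchored span (the `()` span, else the whole SV):
`exact` — span equals an ROI; `partial` — exactly one breakend strictly
inside an ROI; `contained` — span within an ROI; `containing` — ROI within
span; `terminal` — one breakend at a chromosome end; `whole_chromosome` —
span covers the chromosome (lengths rescaled); `blacklist` — no breakend
of the SV strictly inside a blacklisted interval. A standalone checker
(`auditPlacement()`), separate from the sampler, re-verifies each mode by
direct coordinate comparison and backs the placement test sweeps.

Booking rules worth knowing: dispersion intervals are *not* booked, so
other SVs may be placed inside them; copy-source letters *are* booked, so
no later SV can rewrite the template of a duplication; insertion junctions
are booked as 1 bp points; and a floor of 1 bp is always applied to the
inter-SV breakend distance so that no two SVs share a breakend — this
keeps the truthset unambiguous to replay. The distance floor applies
across haplotypes even when cross-haplotype overlap is enabled.

## Genome synthesis and outputs

Each placed SV resolves to a table of atomic records (deletions,
inversions, tandem duplications, insertions-with-provenance, SNPs) in
0-based half-open coordinates. The haplotype builder walks each chromosome
left to right, emitting identity blocks between SVs and the SV's blocks at
its site; copies always read from the *original* reference. The resulting
assembly tiles every synthetic contig exactly and is what the PAF emitter
serializes (novel-sequence blocks have no reference provenance and are
skipped by default). Conversion to 1-based coordinates happens only at VCF
emission: POS is the padding base before the event (a `ZSTART` flag marks
events at position 0), complex SVs span multiple records linked by
`PARENT_SVID`, and every record carries the rule (`GRAMMAR`), its symbol
and operation, and copy provenance (`SRC_*`) or novel sequence (`INSSEQ`).

The package ships a deliberately naive replay oracle
(`replayOracle()`) that rebuilds both haplotypes from the emitted VCF by
plain string splicing — descending coordinate order, point insertions
after interval operations at the same coordinate, descending slot order
among coinciding insertions. It shares no code with the builder and is the
independent second route in the equivalence tests.

## Synthetic data

`fixtureSpec()`/`makeReference()` generate the test references: i.i.d.
random background sequence at a chosen GC fraction (default 0.41, a
genome-wide human-like value), labeled ROI intervals placed without
overlap at a minimum spacing, and tandem-repeat loci with planted motifs.
`caseStudyFixture()` builds the desk-scale analogue of a repeat-annotated
human chromosome: 10 Mb with a LINE-1-like track (200 intervals of 6–7 kb)
and a satellite-like track (150 intervals of 2–4 kb).
`caseStudyConfigs()` writes the three deletion scenarios over it
(blacklisted unique regions with 500 deletions; exact placement on
L1HS-like boundaries and deletions containing satellite-like intervals
with 100 each — the constrained scenarios are scaled because a 10 Mb
fixture cannot supply 500 suitable ROIs).

These fixtures emulate coordinates and annotation structure, not sequence
biology: ROI tracks are random sequence, so mappability, repeat homology
and GC structure of real repeats are absent. Passing tests therefore
demonstrate the correctness of the simulator's bookkeeping (grammar,
placement, synthesis, serialization) on realistic scales — not that
downstream callers would behave as they do on real genomes.

## Numerical and edge-case choices

* Coordinates are 0-based half-open internally; BED is read natively and
  1-based conversion happens only in the VCF writer.
* Derived lengths round to nearest with a 1 bp floor.
* `partial` requires the non-anchored breakend to lie outside the chosen
  ROI; "inside" is strict (a breakend exactly on an ROI boundary is
  outside), consistently for `partial` and `blacklist`.
* Inter-chromosomal dispersions (one `_` allowed) re-home all segments
  after the dispersion onto a uniformly chosen other chromosome at an
  unconstrained position.
* Copy counts for `+` tokens are drawn independently per token and per SV
  instance.
* Novel insertion file mode uses a whole record when one has the exact
  length, otherwise a uniform subsequence of a sufficiently long record.
* Tandem-repeat contractions larger than the locus's copy number are
  placement failures, not truncations.
* SNP ALT alleles are drawn uniformly from the three non-reference bases;
  adjacent SNPs are prevented by the 1 bp breakend floor.

## Problem sizes in the shipped tests

The suite exercises: the full 500-deletion scenario on a 10 Mb reference;
100 randomized genomes (two contigs, ~80 kb, up to 12 SVs drawn across all
26 types) checked byte-for-byte against the replay oracle; a sweep of
>1000 constrained placements across all seven modes with the standalone
audit; VCF validation with bcftools and `VariantAnnotation`; PAF liftover
base-agreement checks; and byte-identical determinism of all outputs under
a fixed seed. These sizes were chosen as the smallest that still give the
constraint machinery realistic occupancy pressure.

## Known limitations

* Ploidy is fixed at 2; no somatic clone mixtures or multi-sample output.
* One dispersion per rule when inter-chromosomal; nested anchors,
  multi-character symbols and arithmetic inside rules are not supported.
* Placement is the greedy heuristic described above — there is no global
  optimization, so heavily constrained configurations can fail even when a
  global solution exists; increasing `max_placement_attempts` or ROI
  supply is the remedy.
* PAF records novel insertions only optionally (they have no reference
  provenance), so liftover is defined on reference-origin blocks.
* Imported VCFs must use this package's dialect (or simple symbolic
  records) — arbitrary caller VCFs are not a supported input.
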