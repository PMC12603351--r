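# svforge

Grammar-based structural variant (SV) simulation for R.

Benchmarking and training SV discovery methods needs genomes whose variants
are known exactly. svforge transforms a reference genome (FASTA) into a
synthetic **diploid** genome carrying user-specified SVs and emits the full
truthset: two haplotype FASTAs, a linked VCF describing every event, a pair
of PAF files lifting synthetic coordinates back to the reference, and a
statistics summary. It is aimed at developers of SV callers, read aligners
and learning-based variant models who need diverse, well-controlled
benchmark genomes.

## The rearrangement grammar

Each SV category is the 4-tuple **(t, D, C, n)**: a type *t*, breakend
distance ranges *D*, placement constraints *C* and a count *n*. The type is
either one of 26 predefined classes (`DEL`, `INV`, `dDUP`, `delINVdel`,
`rTRA`, ...) or a custom *rearrangement expression* mapping reference
intervals (capital letters) to an alternative allele structure:

| expression  | meaning                                  |
|-------------|------------------------------------------|
| `ABC→AC`    | deletion of B                            |
| `A→a`       | inversion of A (lowercase = inverted)    |
| `ABC→AABCC` | tandem duplication of A and C            |
| `ABC→ACB`   | translocation of B                       |
| `A_→A_A`    | dispersed duplication of A (`_` = dispersion interval) |
| `A→AB`      | novel insertion of B                     |
| `A(B)C→b`   | anchored delINVdel: the `()` span is the one bound by placement constraints |

A `+` suffix draws a variable copy number from a configured range, and
dispersions may be made inter-chromosomal.

Placement is context-aware: every category can be constrained against
labeled regions of interest (BED) with modes `exact`, `partial`,
`contained`, `containing`, `terminal`, `whole_chromosome` and `blacklist`,
plus a global minimum inter-SV breakend distance. SVs are placed greedily,
most restrictive constraints first, by rejection sampling against an
occupied-interval index per haplotype.

## Worked example

```r
library(svforge)

# a reproducible 1 Mb synthetic reference with a LINE-1-like ROI track
fx <- makeReference(
  fixtureSpec(chromLengths = c(chr1 = 1e6),
              roiPlan = data.frame(label = "L1HS", count = 20, minLen = 6000,
                                   maxLen = 7000, spacing = 3000),
              seed = 42),
  "example")

writeLines(c(
  "reference: reference.fa",
  "overlap_regions: [L1HS.bed]",
  "min_intersv_dist: 1000",
  "variant_sets:",
  "  - type: DEL",
  "    number: 10",
  "    length_ranges: [[1000, 10000]]",
  "    overlap_mode: exact",
  "    overlap_region_type: [L1HS]",
  "  - type: delINVdel",
  "    number: 2",
  "    length_ranges: [[500, 1000], [2000, 4000], [500, 1000]]"
), "example/sim.yaml")

res <- simulateGenome("example/sim.yaml", "example/out", seed = 7)
res
#> SimulationResult: 12 SVs on 1 reference contig(s)
#>   hapA_fasta: example/out/hapA.fa
#>   ...
placedSVs(res)[[11]]
#> PlacedSV sv11: delINVdel on haplotype(s) 0
#>   A: chr1:479510-480357
#>   B: chr1:480357-483445
#>   C: chr1:483445-484275
```

The ten deletions land exactly on L1HS interval boundaries (their VCF
records show e.g. `POS=55455 ... END=61512;SVLEN=-6057` matching an ROI of
width 6057), and the complex `delINVdel` events are emitted as three linked
records sharing a `PARENT_SVID` with the grammar annotation
`GRAMMAR=ABC->b`. `example/out/stats.tsv` summarises the run:

```
metric        group        value
count         DEL          10
size_min      DEL          6005
size_mean     DEL          6318.6
size_max      DEL          6605
count         delINVdel    2
length_delta  chr1_hapA    -59648
length_delta  chr1_hapB    -50294
```

`length_delta` is the exact base count by which each synthetic haplotype
differs from the reference; here haplotype A carries 9 of the deletions and
one delINVdel.

A command-line front end is installed with the package
(`exec/svforge`): `svforge simulate --config sim.yaml --output-dir out
[--seed N]`, `svforge list-types`, `svforge make-fixtures`.

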