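---
title: "Quantifying barcode-swap chimerism in pool-packaged AAV libraries"
author: "aavchimera maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying barcode-swap chimerism in pool-packaged AAV libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aavchimera)
```

## The problem

Complex AAV libraries carry two barcodes (BC1, 15 nt; BC2, 16 nt)
flanking an insert, with uniquely associated BC1--BC2 pairs established
in the parental plasmid library. If packaging shuffles genetic material
between co-packaged genomes, a sequenced genome can carry BC1 from one
parental molecule and BC2 from another -- a *discordant* pair within a
single read. The fraction of discordant pairs among reads with both
barcodes validated is a direct, sequence-level readout of chimerism.
This package implements the full measurement chain:

1. **Dictionary construction** (`buildDictionary()`): from short-read
   association data, a validated set of unique BC1--BC2 pairs.
2. **Long-read parsing** (`parseReads()`): signpost-anchored feature
   extraction from noisy nanopore reads, demultiplexing, exact
   dictionary matching and length classification.
3. **Swap statistics** (`tallySwaps()`, `bootstrapFdr()`,
   `fisherExact2x2()`): per-library discordant fractions with bootstrap
   uncertainty and stratified exact tests.
4. **Insert annotation** (`alignSegments()` and friends): simple /
   composite / unmapped categorization and pairwise homology calls
   against a shuffled null.
5. **Simulation** (`simulatePackagedReads()` and friends): synthetic
   libraries with known ground truth, so every stage is testable
   without external data.

## The dictionary model

Association reads are piled up into (BC1, BC2, reads) counts. Per-side
totals (over pairs with at least `pileup_min = 3` reads) follow a
trimodal distribution: a low class (totals at most 5 reads) treated as
sequencing/PCR error and excluded outright; a mid class carrying the
bulk of coverage; and a high class of jackpotted clones. The mid/high
boundary is data dependent and therefore a required argument
(`high_cutoff`); `proposeHighCutoff()` suggests the valley of the
log10-total histogram. The filters, in order:

* an optionally configured **dominant artifact BC2** is removed together
  with every barcode within Levenshtein distance 2;
* barcodes with **10 or more consecutive G** or containing the
  side-specific **truncation signature** (`ATTAAAC` after BC1,
  `TAGCGCG` after BC2 -- the constant sequence read into when the
  barcode is short) are removed;
* mid barcodes within distance 2 of any (pre-correction) high barcode
  are pruned as likely errors of abundant clones;
* high barcodes are **error-corrected on the Levenshtein graph**
  (distance <= 2 edges): each connected component keeps its
  most-abundant member, and components whose max/min count fold change
  is below 10 -- or whose maximum is tied -- are discarded as ambiguous.

Pairs with at least 2 reads whose barcodes are in both valid sets are
kept only when, on *both* sides, strictly more than 99% of that
barcode's reads (summed over pairs passing the read floor) belong to
this single pair. The uniqueness denominator is computed after the pair
read floor; this is declared rather than configurable because the two
conventions differ only for barcodes dominated by singleton pairs,
which the floor is designed to remove.

## Long-read parsing

Reads are scanned for the four constant **signposts** flanking the
barcodes with a vectorized affine-gap Smith--Waterman (match +2,
mismatch -2, gap open -3, gap extend -1; the first gapped base costs
the opening penalty). A hit is retained at identity >= 75%, defined as
matching bases over signpost length. Two numerical choices deserve
note:

* **Ambiguity.** A signpost with a second, non-overlapping hit is only
  flagged ambiguous (and the read rejected) when that hit reaches the
  identity threshold *at a comparable score* (>= 90% of the best).
  Short signposts accumulate scattered partial matches by chance; a
  low-score scatter is not a plausible alternative location, whereas a
  near-tie indicates a genuinely duplicated anchor.
* **Strand handling.** Hits are searched per strand; layout validation
  reduces to the best hit per signpost, fails on cross-strand score
  ties, and then requires all four on one strand in the
  strand-appropriate order (BC1 block before BC2 on `+`). The parsing
  pipeline then canonicalizes orientation: reads whose signposts score
  best on the minus strand are reverse complemented and re-scanned, so
  a read and its reverse complement take identical alignment paths and
  every extracted feature mirrors exactly (optimal-alignment
  tie-breaking is otherwise direction dependent).
* **Seeded scanning.** Signposts are first located by exact 11-mer
  seeds (also used to skip the strand without any seed); dynamic
  programming runs only in windows around clustered seed diagonals,
  with symmetric slack so results mirror under reverse complement. The
  full-read scan remains the fallback whenever seeding finds nothing
  convincing, so heavily errored or signpost-less reads are judged by
  the same rule as before -- seeding changes where the aligner looks,
  not what it accepts.

Features are extracted from intervals set by the signpost positions
(all coordinates 0-based half-open; minus-strand reads are
reverse-complemented first so features are reported in the forward
frame). The 10-nt library index sits immediately interior to the right
BC2-upstream signpost after the 34-nt partial Nextera R2 handle, with a
configurable spacer (`index_offset`, default 0) because the assembled
map between insert and right signpost is not uniquely determined by the
published layout. BC-to-BC length is measured from the first BC1 base
to the last BC2 base; since windows are both derived and applied under
this convention, the choice of endpoints cancels in classification.

Demultiplexing assigns the library whose index is nearest in
Levenshtein distance when the best distance is at most 1 and the margin
to the second best is at least 2. Dictionary matching is exact -- no
error tolerance -- and concordance is only defined when both barcodes
are separately valid. "Full length" BC-to-BC windows are nearest-rank
1%/99% quantiles of a control length distribution (the digest control
in real data; a zero-swap simulation in tests); ITR-to-ITR windows are
fixed per library. A read enters the swap denominator only if it passes
layout validation, demultiplexes unambiguously, has both barcodes
valid, and is full length BC-to-BC.

**Dimer reads** (forward pass + hairpin `GCGGACCGAGCGGCCGC` + reverse
pass) are detected by read length (>= 1.6x expected), a hairpin match
near the midpoint, and reverse-complement similarity of the flanks; a
hairpin weakened beyond `max_hairpin_dist` edits (up to twice that) is
accepted only with strong flank similarity, which keeps detection above
95% at 5% read noise without admitting normal reads. Dimers are parsed
from their forward pass and flagged so dimer/non-dimer comparisons
remain possible.

## Swap statistics

The resampling unit is the read, drawn with replacement within each
sample independently (equivalently, the discordant count is binomial at
the observed fraction) -- the standard nonparametric bootstrap matching
per-sample error bars. Intervals are nearest-rank 20th--80th
percentiles of the resampled discordant fraction. The one-sided
bootstrap FDR for "sample A swaps more than sample B" is the fraction
of resamples violating the hypothesized ordering of concordant
fractions. Ties count at half weight, which centers the self-comparison
at 0.5; the strict and weak variants are reported alongside because the
original definition's tie handling is not documented. Fisher's exact
test uses the conventional sum of tables with probability at most the
observed (via `stats::fisher.test`); zero-margin tables return p = 1
with a flag. Every statistical output embeds its seed and resample
count.

## Insert annotation

The module consumes alignment segments from any mapper; a built-in
segmental aligner (iterated best local alignment with the aligned read
interval masked between rounds) covers desk-scale references so tests
need no external binary. Its scoring (match +2, mismatch -4, gap open
-4, extend -2 per base) is deliberately stricter than the signpost
scheme: with permissive gap costs an optimal local alignment can drift
across a splice junction and absorb a second segment, destroying
composite calls.

Filters follow the stated contract: match fraction (matching bases over
alignment length including gaps) strictly greater than 0.65, best
segment per (read, start), pairwise overlap above 50% (of the shorter
segment -- the observed overlap distribution is essentially bimodal at
0%/100%, so the denominator choice is immaterial and is declared in the
output) resolved greedily by match fraction. Two-segment reads on a
circular reference touching the reference start or end within 5 nt are
re-categorized as a single junction-spanning insert; the fix only ever
converts composite to simple. Categories: 0 segments `not_mapped`, 1
`simple`, 2+ `composite`.

Homology between two inserts is called when their local alignment score
exceeds a null threshold: the maximum of `n_null = 1000` alignments of
sampled insert pairs with one member singly shuffled (uniform base
permutation), an empirical null with roughly 1/1000 exceedance. Raw
scores are always exported because any fixed score cutoff is specific
to the scoring scheme. The analytic expectation for the fraction of
insert pairs with shared origin under even random fragmentation is
`f_plasmid^2 * insert_len / plasmid_len`
(`expectedHomologyFraction()`).

## The simulator: what it emulates, and what it does not

`generateBarcodeTruth()` samples barcode sets with a guaranteed minimum
pairwise Levenshtein distance (rejection sampling with an explicit
saturation error). `simulateAssociationReads()` adds Poisson depth,
clonal jackpotting, an optional dominant artifact BC2 and per-base
substitution errors. `simulatePackagedReads()` assembles each read from
the design layout

```
[fillerL][SP1][BC1][SP2 = R1 handle][insert][R2 handle][index][spacer][SP3][BC2][SP4][fillerR]
```

with fillers fixed per design so the nominal total matches the
ITR-to-ITR target (~2.3 kb; ITR sequence itself is out of scope and
enters only through total-length windows). Default designs mirror the
study layout: homologous libraries with one fixed insert (127 / 739 /
2034 nt), non-homologous libraries with size-matched fragments sampled
from a synthetic reference pool (a 5 kb circular "plasmid" and a 50 kb
"genome", both random under a fixed seed and labelled synthetic), with
plasmid-derived fractions 0.65 / 0.19 / 0.15, and a parental design
(881 nt total). Default simulation conditions follow the study where it
states them -- a ~20k-clone bottleneck scale is supported, the dominant
artifact defaults to 2.5% of reads when enabled, off-product and dimer
fractions are 0 unless configured -- and otherwise use one fixed
realistic choice (truncations keep 15--60% of the insert; composite
inserts splice two clearly separated loci).

Two chimera mechanisms are provided. `label_swap` replaces BC2 with a
uniformly drawn other clone's BC2 at an exact per-read rate -- the mode
for parameter-recovery tests. `template_switch` is a *model*, not an
established mechanism: a crossover may occur only inside sequence
tracts shared by two templates (the 67 nt of adapter handles, plus the
insert when inserts are homologous), with `swap_rate` reinterpreted as
the per-base crossover probability, so the realized swap rate is
length- and homology-dependent (`1 - (1 - q)^T`). With q = 5e-4 the
long homologous library swaps at ~65% and its size-matched
non-homologous control at ~3%, reproducing the direction and rough
magnitude of the real contrast; q is a free parameter, not a fitted
value.

ONT noise is i.i.d. per base (substitution / insertion / deletion),
applied last; truth labels always refer to the pre-noise template.
This deliberately omits homopolymer-aware error profiles, ITR secondary
structure, and packaging-efficiency biases -- so passing tests
demonstrate correctness of the measurement chain under a structurally
faithful read model, not calibration against real ONT error spectra.

## Numerical choices and problem sizes

Reproducibility: every stochastic function takes a seed and restores
the caller's RNG; identical config + seed gives byte-identical FASTQ
and truth tables. Quantiles are nearest-rank throughout. Sequence
comparisons are case-insensitive after uppercase normalization, and `N`
never matches, including against another `N`.

The test suite and the acceptance script run at the study's stated
desk scales where given -- 5,000 reads per run across 20 seeds and
three swap rates for parameter recovery, 1,000-pair dictionaries at
depth 30, 10,000 reads per arm for the homology contrast, 1e5 bootstrap
resamples -- and at reduced sizes for supporting property checks
(e.g. null-threshold length scaling uses 60--400 nt inserts), chosen so
the whole suite completes on a single CPU in well under half an hour.

## Known limitations

* The built-in segmental aligner is for desk-scale references; genome
  scale annotation should import segments from a production long-read
  mapper (any source producing the segment table works).
* The mid/high abundance boundary must be supplied; the histogram
  valley helper is a heuristic, not an estimator with guarantees.
* `template_switch` is a phenomenological crossover model; agreement in
  direction with real data is not evidence for a molecular mechanism.
* Barcode extraction windows for association reads default to the
  published run layout (BC1 = read2 cycles 1-15 of a 16-cycle window,
  BC2 = read1 cycles 21-36) and are configurable; the 15 vs 16 cycle
  discrepancy for BC1 is surfaced as a parameter rather than resolved.
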