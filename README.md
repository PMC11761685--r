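# aavchimera

Quantifies chimerism ("barcode swapping") in complex AAV libraries that
are packaged as a pool. Each library member carries two barcodes, BC1
(15 nt) and BC2 (16 nt), whose valid pairings are established in the
parental plasmid library. A packaged genome whose long read contains
BC1 from one parental molecule and BC2 from another is a chimera; the
fraction of such *discordant* pairs, among reads where both barcodes
match the validated dictionary exactly, measures recombination during
packaging.

For a swap tally with $n_c$ concordant and $n_d$ discordant reads the
package reports $\hat f = n_d / (n_c + n_d)$ with nearest-rank
20th–80th bootstrap percentile intervals (reads resampled with
replacement), one-sided bootstrap false discovery rates between samples
(the fraction of $10^5$ paired resamples violating the hypothesized
ordering of concordant fractions; ties at half weight), and stratified
Fisher's exact tests. The expected fraction of insert pairs with shared
plasmid origin under even random fragmentation is
$f_\mathrm{plasmid}^2 \cdot \ell_\mathrm{insert} / L_\mathrm{plasmid}$.

The package covers the whole measurement chain:

* `buildDictionary()` — validated unique BC1–BC2 pairs from short-read
  association counts (abundance classes, artifact filters,
  Levenshtein-graph error correction, strict >99% unique-pairing rule);
* `parseReads()` — signpost-anchored parsing of nanopore long reads
  (Smith–Waterman signpost search, layout validation, demultiplexing by
  10-nt insert index, exact dictionary matching, length windows, hairpin
  dimer splitting);
* `tallySwaps()`, `bootstrapInterval()`, `bootstrapFdr()`,
  `fisherExact2x2()` — swap statistics;
* `alignSegments()`, `categorizeInsert()`, `callHomology()`,
  `expectedHomologyFraction()` — insert annotation
  (simple/composite/unmapped) and homology calls against a
  shuffled-null score threshold;
* `simulatePackagedReads()` and friends — ground-truth simulators for
  every stage (label-swap and template-switch chimera models,
  off-products, dimers, ONT-like noise).

See the vignette (`vignettes/barcode-swap-analysis.Rmd`) for the models
and all numerical conventions.

## Worked example

Simulate a 1,000-clone short-insert library packaged with a 20% swap
rate under ONT-like noise, then recover the rate through the full
pipeline:

```r
library(aavchimera)

truth <- generateBarcodeTruth(1000, min_pairwise_dist = 5, seed = 1)
design <- defaultLibraryDesigns()$short_homologous
cfg <- simulationConfig(n_reads = 5000, swap_rate = 0.2,
                        sub_rate = 0.01, ins_rate = 0.0025,
                        del_rate = 0.0025, seed = 5)
sim <- simulatePackagedReads(design, truth, cfg)

dict <- new("PairDictionary", valid_bc1 = truth$bc1,
            valid_bc2 = truth$bc2,
            pairs = data.frame(bc1 = truth$bc1, bc2 = truth$bc2),
            uniqueness_threshold = 0.99, provenance = list())
pr <- parseReads(setNames(sim$reads$seq, sim$reads$read_id), design,
                 dict = dict, bc_to_bc_window = c(200, 320))
pr$retention
#>         input   layout_pass demultiplexed      bc_valid full_bc_to_bc
#>          5000          4943          4567          2578          2578
tallySwaps(pr$parsed, by = character(0))
#>    n_concordant n_discordant fraction_discordant
#> 1:         2053          525           0.2036462
```

The retention cascade mirrors the real filter chain: reads failing
layout validation, demultiplexing, exact barcode matching or the
full-length window never enter the denominator (barcodes hit by any
noise fail the exact-match rule, which is why about half the reads
drop there at 1% error). The recovered discordant fraction (0.2036)
agrees with the injected swap rate (0.2) within binomial error; with
noise disabled the recovery is exact.

`expectedHomologyFraction(0.65, 100, 5000)` returns `0.00845`
(≈ 0.8%): with 65% of inserts plasmid-derived and 100-nt inserts from a
5-kb plasmid, fewer than 1% of insert pairs share an origin — the
analytic cross-check for the near-absence of homology in tagmented
control libraries.

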