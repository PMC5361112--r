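# paleomito

Consensus calling and clade assignment for ancient mitochondrial genomes
assembled from pooled, barcoded sequencing libraries.

## The problem

Ancient-DNA libraries yield short (30–150 bp), damaged fragments. Without
UDG treatment, cytosine deamination reads as C→T near the 5′ end of each
fragment (and G→A near the 3′ end), sequencing is error-prone, PCR
produces many copies of each original molecule, and pooling barcoded
libraries in one capture reaction lets a small fraction of read copies
"bleed" to the wrong sample's barcode. `paleomito` reconstructs reliable
per-sample mitogenome consensus sequences from this material and places
them into named mitochondrial clades:

1. **Filter** — keep reads ≥ 30 bp with ≤ 5 bases below Q10.
2. **De-multiplex conservatively** — group reads by exact alignment
   (start, end); discard clusters seen < 3 times; assign each surviving
   cluster wholly to its strictly most frequent barcode, discarding ties.
   Because a bleed copy lands in a cluster dominated by its true sample,
   it is outvoted instead of contaminating another sample.
3. **Collapse PCR duplicates** — one consensus read per coordinate
   cluster (per-column majority, quality tie-break, N on residual ties).
4. **Call consensus twice** — per-site majority calling from the
   unique-read pileup under two policies: *relaxed* (depth ≥ 3, majority
   > 1/3, genome included if ≤ 33% N) and *strict* (depth ≥ 10, majority
   > 90%, ≤ 20% missing). For a site with depth *d* and top-base count
   *m*, the call is the top base iff *d* ≥ d<sub>min</sub> and
   *m*/*d* > f (exclusive, evaluated in exact rational arithmetic),
   else N. The strict call is provably N-or-equal to the relaxed call.
5. **Partition** — cut genomes into the four mitogenome categories
   (protein-coding, control region, tRNA, rRNA), reverse-complementing
   reverse-strand genes, and export FASTA + NEXUS `charset` blocks.
6. **Assign clades** — p-distance (pairwise deletion) neighbor-joining
   with bootstrap; a query joins clade X iff the smallest supported edge
   (≥ 70% by default) groups it exclusively with X-labeled references.

A ground-truth simulator (`simulate_reads()`, `pool_with_bleed()`,
`simulate_batch()`) generates barcoded ancient-DNA read sets with known
haplotypes, damage, duplicates and bleeding, so the whole chain is
testable without external data.

## Worked example

```r
library(paleomito)

ref   <- generate_reference(2000, n_features_per_category = 1, seed = 7)
batch <- simulate_batch(ref, n_samples = 5, n_substitutions = 25,
                        params = simulation_params(), seed = 11)
res   <- run_pipeline(batch$pool$reads, ref)
print(res)
#> pipeline_result: 5 sample(s); 2905/4911 cluster(s) retained
#>   S4: 603 unique reads; relaxed 0.7%N(in), strict 3.4%N(in)
#>   S3: 566 unique reads; relaxed 1.1%N(in), strict 5.1%N(in)
#>   S1: 559 unique reads; relaxed 0.5%N(in), strict 5.3%N(in)
#>   S2: 590 unique reads; relaxed 0.9%N(in), strict 4.5%N(in)
#>   S5: 587 unique reads; relaxed 1.2%N(in), strict 2.8%N(in)
```

Each sample's ~1,700 retained read copies collapse to 560–600 unique
molecules (≈ 17× usable coverage after the occurrence-≥3 filter removes
singleton/doubleton clusters). The strict consensus masks 3–5% of sites
as N — mostly the reference edges and coverage troughs — yet matches the
true simulated haplotype at 100% of called sites for all five samples;
the relaxed consensus calls more sites (≤ 1.2% N) at the cost of weaker
per-site evidence. Both tiers pass their inclusion bounds, so all five
genomes would enter both alignments.

```r
pa <- concatenate_partitions(
  setNames(lapply(res$samples, function(s) s$strict$sequence),
           names(res$samples)), ref)
write_partitions_nexus(pa, "blocks.nex")
```

Command-line equivalents of every stage live in
`inst/scripts/paleomito-cli.R` (subcommands `simulate`, `demux`, `dedup`,
`call`, `partition`, `assign`).

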