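---
title: "Methods: ancient-DNA mitogenome consensus calling and clade assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancient-DNA mitogenome consensus calling and clade assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Mitochondrial genomes assembled from subfossil bone are built from short,
damaged DNA fragments. Three properties of this material shape every design
decision in `paleomito`:

* **Fragmentation.** Endogenous molecules are mostly 30–150 bp, so a
  mitogenome is reconstructed by tiling many thousands of independent
  fragments against a reference coordinate frame.
* **Cytosine deamination.** In libraries that are not treated with
  uracil-DNA-glycosylase (UDG), deaminated cytosines read as thymines near
  the 5′ end of each fragment (and, on the strand as sequenced, guanines as
  adenines near the 3′ end). These damage-derived substitutions are
  molecule-specific, not sample-specific, so they can be suppressed by
  requiring agreement across independent molecules.
* **Pooled capture.** When many barcoded libraries are enriched and
  sequenced in a single reaction, a small fraction of read copies is
  recorded under the wrong barcode ("barcode bleeding" or index hopping).
  Left unfiltered, a high-coverage sample bleeds a low-coverage ghost of
  itself into every other sample of the batch.

The package implements a conservative pipeline for this setting —
quality/length filtering, coordinate-cluster de-multiplexing, PCR-duplicate
collapse, two-tier consensus calling — plus the two downstream steps needed
to place the resulting genomes in a phylogenetic context: partitioning into
the four functional categories of the mitogenome, and neighbor-joining
clade assignment against labeled reference haplotypes. A ground-truth
simulator makes the whole chain testable end to end.

# Pipeline stages

## Quality and length filter

A read is retained iff it is at least 30 bp long and carries at most five
bases with Phred quality below 10 (`filter_policy()` defaults). The filter
runs **before** clustering, so undersized or low-quality reads never count
toward cluster occurrence. The alternative order (count copies first,
filter later) would let unusable reads rescue clusters past the occurrence
threshold; we consider the stricter order the safer reading and apply it
throughout.

## Coordinate clusters and de-multiplexing

Reads sharing exact alignment start **and** end coordinates are presumed
PCR copies of one original molecule: with random fragmentation, two
independent molecules rarely share both breakpoints, whereas PCR copies
always do. On these clusters the de-multiplexer applies two rules:

1. a cluster observed fewer than 3 times is discarded;
2. a surviving cluster is assigned, whole, to its strictly most frequent
   barcode; a tie for the maximum discards the cluster.

Barcode frequencies are counted **within the cluster**, pooling that
cluster's reads across the batch. This is the only counting universe in
which the tie rule is meaningful, and it is what makes the filter
conservative: a bleed copy sits in a cluster dominated by its true sample,
so it is outvoted instead of founding a spurious cluster in the wrong
sample.

Minority-barcode members of a retained cluster are kept and reassigned to
the winning sample (default). The rationale: a bleed copy *is* a copy of
the winner's molecule, so discarding it would throw away real evidence;
the subsequent duplicate collapse absorbs it into the molecule's consensus
anyway. `demultiplex(..., minority = "drop")` discards them instead for
users who prefer symmetry with the cluster-level discard rules.

## Duplicate collapse

Each retained cluster is collapsed to a single consensus read
(`deduplicate()`). Columns align by offset from the shared start
(the model is substitution-only; indels are out of scope end to end). The
column rule is: majority base over members, excluding Ns; ties broken by
the larger summed Phred quality of the tied bases; a tie that survives the
quality comparison becomes N. Majority-plus-quality-tie-break is the
minimal deterministic completion of "collapse to one consensus", and N
propagates residual ambiguity to the caller, whose depth/majority
thresholds are designed to absorb it. Consensus reads deliberately carry
no per-base qualities: downstream calling counts unique reads, not
quality-weighted evidence.

## Two-tier consensus calling

`build_pileup()` counts A/C/G/T per reference site over unique reads (Ns
contribute neither to counts nor depth). `call_consensus()` then applies a
`calling_policy()`:

| policy  | min depth | majority bound (exclusive) | max N fraction (inclusive) |
|---------|-----------|----------------------------|----------------------------|
| relaxed | 3         | 1/3                        | 0.33                       |
| strict  | 10        | 0.90                       | 0.20                       |

A site is called iff its depth reaches the minimum **and** the sole
maximal base exceeds the majority bound; otherwise it is N. A genome is
flagged `included` iff its N fraction (over the full reference length,
uncovered sites counted as N) does not exceed the policy bound.

Two boundary choices deserve emphasis. "Higher than 33%" is implemented as
strictly greater than 1/3 — the figure is shorthand for one-in-three — so
a perfect three-way split is never called; "more than 90%" is likewise
exclusive. Threshold comparisons are done in exact integer arithmetic
(`count * den > num * depth`, with the bound stored as a small rational),
because floating-point evaluation of `depth * (1/3)` misclassifies exact
boundary cases for some depths. Both inclusion bounds are inclusive ("no
more than"). The only non-ACGT output symbol is N; IUPAC ambiguity codes
are never emitted.

The two tiers trade coverage for damage tolerance: the relaxed tier keeps
low-coverage genomes analyzable, while the strict tier's 10×/90% demands
make a damage-derived miscall — which would require most independent
molecules at a site to carry the same deamination — vanishingly unlikely.
The strict call at any site is provably either N or identical to the
relaxed call (the strict conditions imply the relaxed ones); the test
suite verifies this exhaustively for all count vectors up to depth 30.

## Partitions

`concatenate_partitions()` cuts each consensus genome into the four
functional categories of the vertebrate mitogenome — protein-coding genes,
control region, tRNAs, rRNAs — reverse-complementing reverse-strand genes
and concatenating features of one category in ascending reference-start
order. Any fixed order is phylogenetically equivalent, so the simplest
deterministic one is used. Inter-genic positions not covered by a feature
are dropped: the four categories are treated as the exhaustive annotation
scheme. One origin-wrapping feature (`end <= start` on the circular
reference) is supported and extracted as suffix+prefix, flagged in the
coordinate map. Output is per-category FASTA plus a NEXUS file with
`charset` lines — the hand-off format for downstream partitioned dating
analyses, which are out of scope here. Codon-position splitting of the
protein-coding block is left to the downstream tool.

## Clade assignment

Distances are uncorrected p-distances with pairwise deletion: for each
pair, only sites where both sequences carry an unambiguous base are
compared. At intraspecific mitochondrial divergence the p-distance is
essentially linear in the substitution count, so this is the minimal
adequate model; a Jukes–Cantor correction is available via
`model = "jc"`.

`nj_tree()` implements Saitou–Nei neighbor joining from its standard
recurrences. Ties in the Q-matrix minimisation are broken by lexicographic
order of the joined pair's labels, making the output invariant to taxon
input order. Negative branch-length estimates (a known NJ artifact on
noisy matrices) are clamped to zero with the deficit transferred to the
sibling branch, preserving their sum; occurrences are counted on the
returned tree. On additive matrices the algorithm is exact; the tests
verify this against an exhaustive least-squares topology enumeration.

`bootstrap_support()` resamples alignment columns with replacement
(default 100 replicates), rebuilds the tree, and annotates each internal
edge of the full-data tree with the percentage of replicates containing
the same bipartition.

`assign_clade()` formalises "classification by similarity and phylogenetic
grouping": a query receives clade X iff the smallest internal edge with
support ≥ `min_support` (default 70) that separates the query together
with at least one labeled reference from the rest has all its labeled
references sharing label X. Mixed labels inside that smallest group leave
the query `"unassigned"` — the method refuses to guess. The nearest
labeled reference by patristic distance is reported in every case, so a
human reviewer can adjudicate unassigned queries. The support threshold of
70 is a community convention for "supported" bootstrap edges, not a value
with special statistical status; it is exposed as a parameter.

# The simulator and what it does (not) show

`simulate_reads()` emulates a non-UDG, single-end (post read-merging)
ancient-DNA library on a known haplotype:

* fragment lengths: truncated normal, default mean 60 bp, sd 15, bounds
  [30, 150] — typical for permafrost-preserved material;
* unique molecule count: Poisson with mean `coverage × L / E[length]`, so
  the realized unique coverage matches the `coverage` parameter in
  expectation;
* deamination: applied once per molecule (PCR copies inherit it), C→T with
  probability `damage_rate × damage_decay^position` from the 5′ end and
  G→A mirrored from the 3′ end. Defaults 0.1 and 0.5 give a ~10% terminal
  rate decaying geometrically, a standard phenomenological shape for
  non-UDG libraries;
* PCR duplication: `1 + Poisson(duplication_rate)` copies per molecule,
  all sharing the molecule's coordinates (default mean 2 extra copies);
* sequencing error: independent per-copy, per-base substitutions at
  `error_rate` (default 0.002);
* base qualities: fixed Q30 with an optional fraction of low-quality
  bases, so the quality filter can be exercised;
* barcode bleeding (`pool_with_bleed()`): each emitted copy is reassigned
  to a uniformly chosen other barcode with probability `bleed_rate`
  (default 0.02).

Every stage is deterministic given its seed, and a truth table records,
per emitted copy, its molecule, true and observed barcode, and damaged and
erroneous positions.

Deliberate simplifications: no insertions or deletions (the whole pipeline
is substitution-only), no capture bias or coverage waviness, no
origin-spanning fragments by default (they would make the (start, end)
cluster key ambiguous; circular fragment placement can be added behind the
`is_circular` flag but is off), no paired-end structure (reads model the
post-merge state), and damage rates that do not vary between molecules.
Consequently, passing tests demonstrate that the *algorithms* behave as
specified under the stated noise model — they do not certify performance
on real libraries with indel errors, reference bias, or contamination,
none of which the simulator generates.

Default problem sizes used by the validation suite — a 2,000 bp reference,
5 samples at 30× unique coverage, 25 substitutions per haplotype — are
chosen so that every stage sees thousands of clusters and the statistical
checks (3σ rate recovery over ≥10,000 reads) are well powered while a full
run stays interactive on a laptop.

# Numerical and degenerate-input choices

* Threshold comparisons in the caller use exact rational arithmetic (see
  above); all other arithmetic is ordinary double precision.
* NJ Q-matrix ties: lexicographic; NJ negative branches: clamped with
  transfer; 3-taxon trees use the closed form.
* Bootstrap replicates that produce a pair with zero comparable sites
  raise an error rather than being silently skipped; at realistic
  missingness this does not occur.
* Empty inputs: `cluster_reads()` and `deduplicate()` return empty
  results; empty clusters, references, haplotypes, and out-of-bounds
  features or reads raise validation errors naming the offender.
* `demultiplex()` with all clusters discarded returns an empty sample map
  and a complete log; every input read is accounted for in exactly one of
  the two.

# Limitations

The pipeline consumes already-mapped reads and trusts their coordinates;
mapping bias and mapping error are upstream concerns. The duplicate
collapse assumes coordinate identity implies molecular identity, which
breaks down at extreme coverage where independent molecules collide on
both breakpoints (the collapse then merges them — harmless for consensus
calling within one sample, but it deflates duplicate-rate estimates).
Clade assignment is a similarity/grouping heuristic on a distance tree; it
is designed for placing queries into well-separated, pre-defined
mitochondrial clades, not for de novo phylogenetic inference, and it
reports `"unassigned"` rather than extrapolating when support or label
purity is lacking.
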