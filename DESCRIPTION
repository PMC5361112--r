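Package: paleomito
Title: Consensus Calling and Clade Assignment for Ancient Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for assembling mitochondrial consensus genomes from
    pooled, barcoded ancient-DNA sequencing libraries and placing them into
    named clades. Implements conservative coordinate-cluster de-multiplexing
    that guards against barcode bleeding between pooled samples, PCR-duplicate
    collapse into per-molecule consensus reads, two-tier (relaxed and strict)
    pileup-based consensus calling with N-masking and genome inclusion
    verdicts, partitioning of the mitogenome into protein-coding, control
    region, tRNA and rRNA blocks for downstream phylogenetics, and
    neighbor-joining clade assignment with bootstrap support against labeled
    reference haplotypes. A substitution-only read simulator with terminal
    cytosine-deamination damage, PCR duplication and barcode bleeding provides
    ground-truth data for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
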