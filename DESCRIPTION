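Package: cdclminer
Title: Discovery and Metagenomic Profiling of Multi-Component CDC-Like Toxin Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines bacterial genome annotations for loci encoding two- or
    three-component cholesterol-dependent cytolysin-like (CDCL) toxins:
    filters HMM hits at a bit-score cutoff, requires adjacent co-oriented
    genes, classifies lipoprotein (SpII) signal peptides with a lipobox
    heuristic plus an [SA]C rescue scan, clusters the retained proteins at a
    percent-identity threshold, derives locus architecture patterns, builds a
    neighbor-joining tree of cluster representatives, and calls locus
    presence in metagenomic read sets by competitive best-match mapping with
    breadth, read-count, and mean-depth thresholds. Includes a seeded
    synthetic-data generator (genomes with planted loci and rule-violating
    decoys, controlled-identity protein families, read simulation) and small
    numeric reductions for pore-ring stoichiometry, FRET donor-quench
    correction, kinetic-trace normalization, and propidium-iodide positivity
    calling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
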