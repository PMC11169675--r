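---
title: "Mining multi-component CDC-like toxin loci: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining multi-component CDC-like toxin loci: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

Cholesterol-dependent cytolysins (CDCs) are β-barrel pore-forming toxins of
Gram-positive pathogens. Bacteroidota genomes carry distant relatives —
CDC-like proteins (CDCLs) — that operate as 2- or 3-component systems: the
genes sit adjacent on one strand, the products carry lipoprotein (SpII)
signal peptides that put them on the cell surface, and pore assembly works
like the complement membrane attack complex, with one membrane-anchored
large subunit (CDCL^L, roughly 500 aa) recruiting on the order of 30 small
subunits (CDCL^S, roughly 365 aa) into a ring. `cdclminer` implements the
comparative-genomics and metagenomics workflow around these systems, plus
the small numeric reductions used when characterizing the pore itself.

This vignette records the model behind each stage, the tunable parameters
and why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical conventions that make runs
reproducible.

## The discovery funnel

Input is a set of gene records (contig, coordinates, strand, protein
sequence) and an HMM hit table for a thiol-activated-cytolysin-family
profile. The funnel has four stages, each of which only removes genes:

1. **Score/length filter** (`filter_candidates`). A hit survives iff its
   bit score is ≥ `min_bitscore` (default 25, the Pfam gathering threshold
   for the family model), it is not flagged partial, and its protein length
   lies in `len_window` (default 100–700 aa — the observed family range is
   117–674 aa, and the window brackets it without being tuned to it). All
   bounds are inclusive.
2. **Adjacency grouping** (`group_adjacent`). Within each (genome, contig,
   strand) subset, candidates sorted by start coordinate form maximal runs
   where every consecutive intergenic gap is at most `max_gap`. "Near each
   other" has no published definition; the default of 5,000 bp is permissive
   enough for co-transcribed genes with short intergenic regions while not
   merging unrelated operons, and it is a plain parameter. Overlapping ORFs
   count as gap 0 (overlaps are common in operons). Runs of one gene are
   reported as singletons, not loci; runs longer than `max_run` (default 3,
   the largest arity observed for these systems) are truncated to the first
   `max_run` genes with a warning — longer runs are anomalies to surface,
   not crash on. Computing runs per strand subset means an intervening
   opposite-strand gene cannot break an otherwise adjacent same-strand run;
   this is what makes the grouping maximal.
3. **Signal-peptide classification** (`classify_signal_peptide`). SpII
   (lipoprotein) signal peptides end in a lipobox whose invariant cysteine
   is lipidated after cleavage. The built-in heuristic calls SpII when
   (a) a lipobox `[LVI][ASTVI][GAS]C` places its cysteine at 0-based index
   10–34, (b) the 8 residues before the lipobox have mean Kyte–Doolittle
   hydropathy > 0 (the hydrophobic h-region), and (c) at least one residue
   at positions 1–7 is K or R (the charged n-region). This is a documented
   stand-in for a full lipoprotein-signal predictor, whose model parameters
   are not public; a precomputed call table can be ingested instead
   (`mine_loci(signal_table = ...)`) when one is available. Proteins that
   miss the heuristic are rescued as `RescuedSpII` when the dipeptide
   `[SA]C` occurs entirely within the first 35 residues — the second-pass
   scan applies to *any* non-SpII call, including would-be SpI proteins.
   The SpI fallback (an A-x-A motif at index 15–30 behind a hydrophobic
   stretch) exists only for tally parity in reports; downstream, the only
   boundary that matters is SpII-or-rescued versus everything else.
4. **Pruning** (`prune_loci`). Genes that are neither SpII nor rescued are
   removed from their locus; loci reduced below two genes are dropped (the
   survivor is an orphan and joins the singleton report); and a locus is
   dropped entirely when any member touches a contig boundary
   (start = 0 or end = contig length), the machine-statable reading of
   "partial protein / edge-of-contig defect". A triplet that loses one
   member this way continues as a pair — the gap rule is not re-checked,
   since the locus was a single transcriptional unit before pruning.

Coordinates are 0-based half-open internally; GFF3's 1-based inclusive
convention is converted exactly once, at the I/O boundary. This is the
single decision that keeps gap arithmetic (`next_start − prev_end`)
off-by-one-free everywhere.

## Clustering and locus patterns

Retained proteins are clustered at a percent-identity threshold (default
0.96). Identity comes from a global Needleman–Wunsch alignment on a 0/1
identity substitution model (match +1, mismatch 0, gap open 10, gap extend
0.5), and is defined as identical aligned pairs divided by **all alignment
columns, terminal gaps included**. Published "percent identity at 96%"
statements rarely pin down the denominator; this choice is the most
conservative one and is explicit and switchable
(`denominator = "shorter_seq"` divides by the shorter sequence length
instead). Clustering is greedy and single-pass, CD-HIT style: sequences in
decreasing length order join the first cluster (in creation order) whose
representative they match at or above threshold, else found a new cluster.
With a 96% threshold and well-separated families the partition does not
depend on this procedural choice; the test suite checks exactly that
property on families mutated to 0.98 identity (must co-cluster) and 0.90
(must not). Two alignment-free prescreens — a length-ratio bound and a
shared-k-mer bound (an alignment with *e* non-identical columns destroys at
most *k* shared k-mers each) — skip provably sub-threshold pairs without
affecting the result.

A locus's **pattern** is the tuple of cluster labels of its genes in
strand-relative 5′→3′ order (minus-strand loci are read right to left), so
`(7, 12)` and `(12, 7)` are distinct architectures. Pattern ids are
assigned by decreasing group size, ties by lexicographic signature. Pairs
are typed by the length ratio shorter/longer: at or above
`similar_ratio_min` (default 0.85) both genes are "M" (similar-sized pair),
otherwise the shorter is "S", the longer "L", and the canonical
architecture has S upstream — upstream-large pairs are flagged anomalous
rather than reinterpreted. The 0.85 default separates the 365/500 archetype
(ratio 0.73, must read as different) from pairs like 336/360 (ratio 0.93,
must read as similar). Size labels for triplets apply the same ratio rule
against the extreme lengths and are marked heuristic: three-component
systems have no published size taxonomy.

## The tree

The cluster-representative tree is neighbor joining on `d = 1 − identity`.
No tree method is canonical for this family; NJ was chosen because it is
deterministic, fast at the 50-leaf scale, and exact on additive matrices —
the property the test suite verifies on random 5–8 leaf trees. Ties in the
Q criterion are broken by the smallest (i, j) index pair and negative
branch-length estimates are clamped to zero with a warning, so runs are
bit-reproducible. Topological agreement with any published figure is *not*
claimed: different alignments and a different method would make that
comparison meaningless.

## Metagenomic presence calling

References are the DNA spans from the first to the last gene of a locus
(flanking DNA excluded; the choice is deliberate and documented here
because the span definition is ambiguous in prose descriptions). Mapping
re-implements competitive best-match semantics: exact k-mer seeds (default
k = 21) against an index over all references, ungapped extension to the
full read length, candidate score = matching bases, and assignment of each
read to the single best candidate provided matches/aln_len ≥ 0.95 — ties
broken by lowest reference index, then leftmost position, then forward
before reverse orientation. Each read is counted at most once, which is the
property that matters for the downstream thresholds. Indels are not
modeled; the read simulator is correspondingly substitution-only. Alignment
fidelity is not the point of this stage — the presence decision is.

A reference is **present** in a sample iff all three hold (inclusive):
breadth ≥ 0.75 (fraction of positions with depth ≥ 1), assigned reads
≥ 20, and mean depth ≥ 5× — mean depth averaged over *all* reference
positions, covered or not ("per reference base"). "Minimum of 20 reads" is
read as 20 assigned reads per reference, not 20 per position. A pattern
counts as detected in a sample when any of its reference loci is present;
with one representative locus per pattern (the default reference set) the
two possible readings coincide. Prevalence percentages are reported to one
decimal, rounding half away from zero.

## The synthetic-data generator

`generate_genomes` emulates the statistical structure the discovery code
cares about, nothing more: multi-contig genomes with planted adjacent
co-oriented gene runs whose products carry constructed leaders (a full
lipobox for SpII, a `[SA]C`-only leader that provably fails the lipobox
heuristic for rescue-only, and a leader with no cysteine or alanine in the
first 35 residues for no-signal), plus one decoy element per genome that
violates exactly one rule: score below 25, partial flag, opposite strands,
gap above `max_gap` (8,000 bp vs the 5,000 bp limit), no signal, or a gene
starting at position 0 of its contig. Unrelated elements on a shared contig
are spaced 6,000 bp apart — above the adjacency limit by construction, so a
decoy can never merge with a planted locus. Protein bodies are uniform
random over the 20 standard residues and genes are back-translated with a
fixed codon table; hit scores for genuine elements are uniform on [60, 300].
Reads are drawn uniformly (count = round(depth · L / read length)), strands
Bernoulli(0.5), substitution errors i.i.d. (0.005 in the shipped
simulations), qualities a constant `I`. Everything is deterministic per
seed.

What this does **not** emulate: real codon usage, GC content, gene density,
paralogs, shared protein families across genomes (each synthetic genome's
families are independent, so pattern groups are mostly singletons),
community abundance structure, indel or quality-correlated sequencing
error. Passing the planted-recovery test therefore shows the *rules* are
implemented correctly — not that the heuristic signal-peptide caller or the
simple mapper would match a specific external tool on real data. The
ingestion paths (precomputed signal tables, external hit tables) exist for
exactly that reason.

## Numerical conventions and assay reductions

* Rounding in the ring-geometry reductions is half away from zero, applied
  to integer nanometres and to the monomer count; under this convention a
  20 nm inner diameter gives a 63 nm circumference and, at 2.1 nm per twin
  β-hairpin, 30 monomers per ring.
* FRET quench correction: `100 · (DA − UA) / (DU − U)`; 100 means no
  quenching. The corrected donor denominator must be positive, otherwise
  the donor signal is not above background and the ratio is refused. When
  replicates exist, correction is applied per replicate before averaging.
* Kinetic traces are scaled so the positive control reads 100 a.u.; the
  transform is linear, so common scale factors cancel.
* PI positivity is a strict inequality against the background (default
  7498 a.u.), per the wording "above the background".
* Problem sizes in the shipped tests and the acceptance script — 50
  synthetic genomes, 10,000 rescue-scan sequences, 1,000 coverage oracle
  cases, 100 random trees, 10 kb mapping references — were chosen as the
  smallest sizes at which every rule and boundary is exercised with a
  comfortable margin; they are package choices, not measurements of any
  particular machine.

## Known limitations

* The lipobox heuristic is intentionally simple; proteins with unusual
  n-regions (no K/R in the first 7 residues) are only recoverable through
  the rescue scan or an ingested call table.
* The mapper's ungapped extension means a single indel in a read costs the
  whole tail of the alignment; with indel-bearing real reads, breadth and
  depth would be underestimated relative to a gapped mapper at the same
  thresholds.
* Greedy clustering is order-dependent in principle; determinism is
  guaranteed (decreasing length, ties lexicographic), closeness to an
  optimal partition only on well-separated families.
* `max_gap`, `similar_ratio_min`, and the presence thresholds are exposed
  parameters; the defaults reproduce the published criteria but carry no
  claim of optimality.
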