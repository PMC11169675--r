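# Independent brute-force oracles used across the suite.

# Rescue-motif oracle: scan every window start i (0-based 0..33) for
# seq[i] in {S, A} followed by C, entirely within the first 35 residues.
brute_rescue <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  for (i in seq_len(min(34L, n - 1L))) {  # 1-based S/A position
    if (chars[i] %in% c("S", "A") && chars[i + 1L] == "C") return(TRUE)
  }
  FALSE
}

# Per-position depth oracle: expand every assignment interval into explicit
# positions and tabulate.
brute_depth <- function(assignments, ref_id, ref_len) {
  a <- assignments[!is.na(assignments$ref_id) &
                     assignments$ref_id == ref_id, , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(a)), function(i) {
    s <- a$ref_start[i] + 1L
    e <- min(a$ref_start[i] + a$aln_len[i], ref_len)
    if (s > e) integer(0) else s:e
  }))
  if (is.null(pos)) pos <- integer(0)
  tabulate(pos, nbins = ref_len)
}

# Ungapped identity oracle, valid for equal-length pairs where the optimal
# alignment is provably gapless (any gap costs >= 10 and can add at most a
# few matches, so pairs within a few substitutions of each other align
# without gaps).
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  mean(av == bv)
}

random_protein <- function(n) {
  paste(sample(Biostrings::AA_STANDARD, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random tree with strictly positive branch lengths; its cophenetic matrix
# is additive by construction, the generating topology is the oracle.
random_additive_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  tr
}

same_unrooted_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Minimal GFF3 + protein FASTA fixture written to tempfiles.
write_gene_fixture <- function(genes, dir = tempfile("fix")) {
  dir.create(dir)
  gff <- file.path(dir, "genome.gff3")
  faa <- file.path(dir, "genome.faa")
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     genes$contig_id, genes$gff_start, genes$gff_end,
                     genes$strand, genes$gene_id))
  writeLines(lines, gff)
  writeLines(as.vector(rbind(paste0(">", genes$gene_id), genes$protein_seq)),
             faa)
  list(gff = gff, faa = faa)
}
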