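# fixed back-translation codon table (one codon per amino acid)
.CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
            E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
            M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
            Y = "TAT", V = "GTT")

.back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1L]]
  paste0(paste(.CODON[aa], collapse = ""), "TAA")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_protein_body <- function(n, exclude = character(0)) {
  pool <- setdiff(Biostrings::AA_STANDARD, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Signal-peptide leaders constructed to hit exactly one classification path:
#  - SpII: lipobox LAGC with Cys at 0-based 16, Lys at positions 1-2,
#    poly-Leu h-region.
#  - rescue-only: no K/R in positions 1-7 (so the lipobox heuristic can
#    never fire) but SC with the Cys at 0-based index 11.
#  - none: no Cys and no Ala anywhere in the first 35 residues, so lipobox,
#    rescue, and the A-x-A SpI fallback are all impossible.
.make_protein <- function(len, signal = c("SpII", "rescue", "none")) {
  signal <- match.arg(signal)
  if (signal == "SpII") {
    leader <- paste0("MKK", strrep("L", 10L), "LAGC")
  } else if (signal == "rescue") {
    leader <- paste0("M", "DEDEDED", "LL", "SC")
  } else {
    leader <- paste0("M", .random_protein_body(34L, exclude = c("C", "A")))
  }
  stopifnot(len > nchar(leader))
  paste0(leader, .random_protein_body(len - nchar(leader)))
}

#' Locus template for the synthetic-genome generator
#'
#' @param protein_len Integer vector (length 2 or 3) of protein lengths in
#'   amino acids (each at least 100).
#' @param gaps Intergenic gaps in bp between consecutive genes (length
#'   `length(protein_len) - 1`, recycled).
#' @param strand `"+"` or `"-"`.
#' @param signal Per-gene signal type, one of `"SpII"`, `"rescue"`,
#'   `"none"` (recycled).
#' @return A `locus_template` list.
#' @export
locus_template <- function(protein_len = c(365L, 500L), gaps = 300L,
                           strand = "+", signal = "SpII") {
  stopifnot(length(protein_len) %in% c(2L, 3L), all(protein_len >= 100L),
            all(gaps >= 0L), strand %in% c("+", "-"))
  structure(list(protein_len = as.integer(protein_len),
                 gaps = rep_len(as.integer(gaps), length(protein_len) - 1L),
                 strand = strand,
                 signal = rep_len(signal, length(protein_len))),
            class = "locus_template")
}

#' Specification for synthetic genome generation
#'
#' Defines how many genomes to build, which locus templates to plant
#' (cycled across genomes), and which rule-violating decoys to add (also
#' cycled). Each decoy violates exactly one discovery rule, so the
#' pipeline's expected fate of every planted element is known.
#'
#' @param n_genomes Number of genomes (default 50).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @param templates List of [locus_template()]s planted one per genome,
#'   cycled. Defaults to the three archetypes: a 365+500 aa small+large
#'   pair, a similar-sized pair, and a triplet, one of them rescue-signal.
#' @param decoy_types Decoy kinds cycled one per genome: `"low_score"`
#'   (bit score below the cutoff), `"partial"` (partial-protein flag),
#'   `"opposite_strand"`, `"far_gap"` (gap above `max_gap`), `"no_signal"`
#'   (neither lipobox nor rescue motif), `"contig_edge"` (gene starting at
#'   position 0 of its contig).
#' @param contig_flank Random DNA padding at contig ends, bp (default 2000).
#' @param element_spacing Random DNA between the planted locus and the decoy
#'   element on a shared contig, bp (default 6000, above the default 5000 bp
#'   adjacency limit so unrelated elements never merge into one run).
#' @param decoy_gap Intergenic gap used by the `"far_gap"` decoy (default
#'   8000, above the default 5000 bp adjacency limit).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(n_genomes = 50L, seed = 1L,
                       templates = list(
                         locus_template(c(365L, 500L)),
                         locus_template(c(336L, 360L)),
                         locus_template(c(365L, 365L, 500L), gaps = c(200L, 200L)),
                         locus_template(c(365L, 500L), strand = "-",
                                        signal = c("rescue", "SpII"))),
                       decoy_types = c("low_score", "partial",
                                       "opposite_strand", "far_gap",
                                       "no_signal", "contig_edge"),
                       contig_flank = 2000L, element_spacing = 6000L,
                       decoy_gap = 8000L) {
  stopifnot(n_genomes >= 1L, all(vapply(templates, inherits, TRUE,
                                        "locus_template")))
  structure(list(n_genomes = as.integer(n_genomes), seed = as.integer(seed),
                 templates = templates, decoy_types = decoy_types,
                 contig_flank = as.integer(contig_flank),
                 element_spacing = as.integer(element_spacing),
                 decoy_gap = as.integer(decoy_gap)),
            class = "plant_spec")
}

# Lay out a run of genes on a growing contig; returns gene rows + sequence.
.place_genes <- function(contig, offset, genome_id, contig_id, id_prefix,
                         protein_len, gaps, strands, signals) {
  n <- length(protein_len)
  gaps <- c(rep_len(gaps, n - 1L), 0L)
  rows <- vector("list", n)
  seq_parts <- character(0)
  pos <- offset
  for (g in seq_len(n)) {
    prot <- .make_protein(protein_len[g], signals[g])
    nt <- .back_translate(prot)
    if (strands[g] == "-") nt <- .revcomp(nt)
    rows[[g]] <- data.frame(
      gene_id = sprintf("%s_g%d", id_prefix, g),
      genome_id = genome_id, contig_id = contig_id,
      start = pos, end = pos + nchar(nt),
      strand = strands[g], protein_seq = prot,
      protein_len = nchar(prot), stringsAsFactors = FALSE)
    seq_parts <- c(seq_parts, nt,
                   if (gaps[g] > 0L) .random_dna(gaps[g]) else character(0))
    pos <- pos + nchar(nt) + gaps[g]
  }
  list(genes = do.call(rbind, rows), seq = paste(seq_parts, collapse = ""),
       end = pos)
}

#' Generate synthetic genomes with planted CDCL loci and decoys
#'
#' Builds `spec$n_genomes` genomes, each carrying one planted locus (from
#' the cycled templates) and one decoy element (from the cycled decoy
#' types), together with a matching HMM hit table and a truth table stating
#' the expected pipeline fate of every planted element. Fully deterministic
#' for a fixed spec (the spec's seed initializes the RNG).
#'
#' @param spec A [plant_spec()].
#' @return A list with `genes` (gene records), `contigs` (`contig_id`,
#'   `genome_id`, `length`, `sequence`), `proteins` (named vector),
#'   `hits` (hit table), and `truth` (`element_id`, `genome_id`,
#'   `contig_id`, `kind`, `rule`, `gene_ids`, `expected` with values
#'   `"retained"`, `"filtered"`, `"singleton"`, or `"dropped"`).
#' @export
generate_genomes <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  flank <- spec$contig_flank
  all_genes <- list()
  all_contigs <- list()
  all_hits <- list()
  all_truth <- list()
  good_score <- function(n) round(stats::runif(n, 60, 300), 1)
  for (gi in seq_len(spec$n_genomes)) {
    genome_id <- sprintf("G%03d", gi)
    tmpl <- spec$templates[[(gi - 1L) %% length(spec$templates) + 1L]]
    decoy <- spec$decoy_types[(gi - 1L) %% length(spec$decoy_types) + 1L]
    c1 <- sprintf("%s_c1", genome_id)

    # planted locus; template fields are strand-relative 5'->3', so genes on
    # the minus strand are laid out in reversed genomic order
    p_len <- tmpl$protein_len
    p_sig <- tmpl$signal
    p_gap <- tmpl$gaps
    if (tmpl$strand == "-") {
      p_len <- rev(p_len)
      p_sig <- rev(p_sig)
      p_gap <- rev(p_gap)
    }
    pl <- .place_genes(NULL, flank, genome_id, c1,
                       sprintf("%s_L", genome_id),
                       p_len, p_gap, rep(tmpl$strand, length(p_len)), p_sig)
    all_truth[[length(all_truth) + 1L]] <- data.frame(
      element_id = sprintf("%s_L", genome_id), genome_id = genome_id,
      contig_id = c1, kind = "locus", rule = "none",
      gene_ids = paste(pl$genes$gene_id, collapse = ","),
      expected = "retained", stringsAsFactors = FALSE)
    all_hits[[length(all_hits) + 1L]] <- data.frame(
      protein_id = pl$genes$gene_id, model_name = "Thiol_cytolysin",
      bit_score = good_score(nrow(pl$genes)), is_partial = FALSE,
      stringsAsFactors = FALSE)

    # decoy element
    dk <- switch(decoy,
      low_score = list(signal = c("SpII", "SpII"), gaps = 300L,
                       strands = c("+", "+"), score = c(20, 20),
                       partial = FALSE, edge = FALSE, expected = "filtered"),
      partial = list(signal = c("SpII", "SpII"), gaps = 300L,
                     strands = c("+", "+"), score = c(80, 80),
                     partial = TRUE, edge = FALSE, expected = "filtered"),
      opposite_strand = list(signal = c("SpII", "SpII"), gaps = 50L,
                             strands = c("+", "-"), score = NULL,
                             partial = FALSE, edge = FALSE,
                             expected = "singleton"),
      far_gap = list(signal = c("SpII", "SpII"), gaps = spec$decoy_gap,
                     strands = c("+", "+"), score = NULL, partial = FALSE,
                     edge = FALSE, expected = "singleton"),
      no_signal = list(signal = c("none", "none"), gaps = 300L,
                       strands = c("+", "+"), score = NULL, partial = FALSE,
                       edge = FALSE, expected = "dropped"),
      contig_edge = list(signal = c("SpII", "SpII"), gaps = 300L,
                         strands = c("+", "+"), score = NULL, partial = FALSE,
                         edge = TRUE, expected = "dropped"),
      stop("unknown decoy type: ", decoy))
    d_contig <- if (dk$edge) sprintf("%s_c2", genome_id) else c1
    d_offset <- if (dk$edge) 0L else pl$end + spec$element_spacing
    dc <- .place_genes(NULL, d_offset, genome_id, d_contig,
                       sprintf("%s_D", genome_id),
                       c(365L, 500L), dk$gaps, dk$strands, dk$signal)
    all_truth[[length(all_truth) + 1L]] <- data.frame(
      element_id = sprintf("%s_D", genome_id), genome_id = genome_id,
      contig_id = d_contig, kind = "decoy", rule = decoy,
      gene_ids = paste(dc$genes$gene_id, collapse = ","),
      expected = dk$expected, stringsAsFactors = FALSE)
    score <- if (is.null(dk$score)) good_score(nrow(dc$genes)) else dk$score
    all_hits[[length(all_hits) + 1L]] <- data.frame(
      protein_id = dc$genes$gene_id, model_name = "Thiol_cytolysin",
      bit_score = score, is_partial = dk$partial, stringsAsFactors = FALSE)

    # assemble contigs
    if (dk$edge) {
      c1_seq <- paste0(.random_dna(flank), pl$seq, .random_dna(flank))
      c2_seq <- paste0(dc$seq, .random_dna(flank))
      all_contigs[[length(all_contigs) + 1L]] <- data.frame(
        contig_id = c(c1, d_contig), genome_id = genome_id,
        length = c(nchar(c1_seq), nchar(c2_seq)),
        sequence = c(c1_seq, c2_seq), stringsAsFactors = FALSE)
      all_genes[[length(all_genes) + 1L]] <- rbind(pl$genes, dc$genes)
    } else {
      c1_seq <- paste0(.random_dna(flank), pl$seq,
                       .random_dna(spec$element_spacing),
                       dc$seq, .random_dna(flank))
      all_contigs[[length(all_contigs) + 1L]] <- data.frame(
        contig_id = c1, genome_id = genome_id, length = nchar(c1_seq),
        sequence = c1_seq, stringsAsFactors = FALSE)
      all_genes[[length(all_genes) + 1L]] <- rbind(pl$genes, dc$genes)
    }
  }
  genes <- do.call(rbind, all_genes)
  rownames(genes) <- NULL
  proteins <- stats::setNames(genes$protein_seq, genes$gene_id)
  list(genes = genes,
       contigs = do.call(rbind, all_contigs),
       proteins = proteins,
       hits = do.call(rbind, all_hits),
       truth = do.call(rbind, all_truth))
}

#' Write synthetic genomes to per-genome FASTA/GFF3/protein files
#'
#' @param gen Output of [generate_genomes()].
#' @param outdir Output directory (created if needed). Per genome:
#'   `<genome>.fna`, `<genome>.gff3`, `<genome>.faa`; plus `hits.tsv`
#'   (minimal 4-column dialect) and `truth.tsv`.
#' @return `outdir`, invisibly.
#' @export
write_genomes <- function(gen, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (genome_id in unique(gen$genes$genome_id)) {
    g <- gen$genes[gen$genes$genome_id == genome_id, , drop = FALSE]
    ctg <- gen$contigs[gen$contigs$genome_id == genome_id, , drop = FALSE]
    write_fasta(stats::setNames(ctg$sequence, ctg$contig_id),
                file.path(outdir, paste0(genome_id, ".fna")), type = "DNA")
    write_fasta(stats::setNames(g$protein_seq, g$gene_id),
                file.path(outdir, paste0(genome_id, ".faa")), type = "AA")
    write_gff3(g, file.path(outdir, paste0(genome_id, ".gff3")))
  }
  utils::write.table(gen$hits, file.path(outdir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(gen$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Extract the nucleotide reference spanning a locus
#'
#' Returns the contig DNA from the start of the first to the end of the
#' last gene of a locus (inclusive), the unit used as a mapping reference.
#'
#' @param locus_genes Gene rows of one locus.
#' @param contigs Contig table with `contig_id` and `sequence`.
#' @return A single nucleotide string.
#' @export
locus_reference <- function(locus_genes, contigs) {
  ctg <- contigs$sequence[match(locus_genes$contig_id[1L], contigs$contig_id)]
  substr(ctg, min(locus_genes$start) + 1L, max(locus_genes$end))
}

#' Mutate a sequence to a target ungapped identity
#'
#' Substitutes `round((1 - target_identity) * nchar(seq))` positions, chosen
#' without replacement, each to a residue different from the original, so
#' the realized ungapped identity equals the target to within `1/nchar(seq)`.
#'
#' @param seq Protein (or nucleotide) string.
#' @param target_identity Fraction in (0, 1].
#' @param seed RNG seed.
#' @param alphabet Residue alphabet for replacements (default the 20
#'   standard amino acids).
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, target_identity, seed,
                            alphabet = Biostrings::AA_STANDARD) {
  stopifnot(target_identity > 0, target_identity <= 1)
  set.seed(seed)
  n <- nchar(seq)
  n_sub <- round((1 - target_identity) * n)
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  pos <- sample.int(n, n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate substitution-only reads at a target depth
#'
#' Draws `round(target_depth * ref_len / read_length)` reads with start
#' positions uniform over the valid range, strands Bernoulli(0.5)
#' (reverse-strand reads are reverse-complemented), and i.i.d. substitution
#' errors at the given rate. Deterministic per seed. Qualities, when
#' written by [write_fastq()], are a constant `I` and ignored downstream.
#'
#' @param ref Reference nucleotide string.
#' @param target_depth Mean fold coverage to simulate.
#' @param read_length Read length in bp (at least 31, at most `nchar(ref)`).
#' @param substitution_rate Per-base substitution probability in \[0, 0.1\].
#' @param seed RNG seed.
#' @return A `data.frame` with `read_id`, `sequence`, `true_start`
#'   (0-based on the reference), `true_strand`.
#' @export
simulate_reads <- function(ref, target_depth, read_length = 100L,
                           substitution_rate = 0, seed = 1L) {
  stopifnot(read_length >= 31L, read_length <= nchar(ref),
            substitution_rate >= 0, substitution_rate <= 0.1)
  set.seed(seed)
  ref_len <- nchar(ref)
  n_reads <- round(target_depth * ref_len / read_length)
  starts <- sample.int(ref_len - read_length + 1L, n_reads, replace = TRUE) - 1L
  strands <- ifelse(stats::runif(n_reads) < 0.5, "+", "-")
  bases <- c("A", "C", "G", "T")
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    s <- substr(ref, starts[i] + 1L, starts[i] + read_length)
    if (substitution_rate > 0) {
      hit <- which(stats::runif(read_length) < substitution_rate)
      if (length(hit) > 0L) {
        chars <- strsplit(s, "")[[1L]]
        for (p in hit) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
        s <- paste(chars, collapse = "")
      }
    }
    if (strands[i] == "-") s <- .revcomp(s)
    seqs[i] <- s
  }
  data.frame(read_id = sprintf("read%05d", seq_len(n_reads)),
             sequence = seqs, true_start = starts, true_strand = strands,
             stringsAsFactors = FALSE)
}
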