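#' Read gene annotations from GFF3 plus a protein FASTA
#'
#' Parses gene/CDS features from a GFF3 file and attaches the corresponding
#' protein sequences by matching feature `ID` attributes against protein
#' FASTA headers. Coordinates are converted from the GFF3 convention
#' (1-based, inclusive) to the package-internal convention (0-based,
#' half-open); all interval arithmetic elsewhere in the package assumes the
#' internal convention and conversion happens only at this I/O boundary.
#'
#' @param gff_path Path to a GFF3 file whose gene/CDS features carry `ID`
#'   attributes matching the protein FASTA headers.
#' @param protein_fasta_path Path to a protein FASTA file. Header text after
#'   the first whitespace is ignored.
#' @param genome_id Genome identifier recorded on every returned record.
#'   Defaults to the GFF3 file name without extension.
#' @param feature_types GFF3 feature types treated as genes (default
#'   `c("gene", "CDS")`; when both exist for an ID the first occurrence wins).
#'
#' @return A `data.frame` of gene records sorted by (contig_id, start) with
#'   columns `gene_id`, `genome_id`, `contig_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"` or `"-"`), `protein_seq`, `protein_len`.
#' @export
read_gff3_with_proteins <- function(gff_path, protein_fasta_path,
                                    genome_id = NULL,
                                    feature_types = c("gene", "CDS")) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gff3?|gff)$", "", basename(gff_path))
  }
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L) stop("no gene/CDS features found in ", gff_path)
  ids <- as.character(gr$ID)
  keep <- !duplicated(ids)
  gr <- gr[keep]
  ids <- ids[keep]
  if (anyNA(ids)) stop("GFF3 feature without an ID attribute in ", gff_path)
  strand <- as.character(BiocGenerics::strand(gr))
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("features with undefined strand (must be '+' or '-'): ",
         paste(ids[bad], collapse = ", "))
  }
  prot <- Biostrings::readAAStringSet(protein_fasta_path)
  names(prot) <- sub("\\s.*$", "", names(prot))
  missing <- setdiff(ids, names(prot))
  if (length(missing) > 0L) {
    stop("protein sequence missing for CDS feature(s): ",
         paste(missing, collapse = ", "))
  }
  genes <- data.frame(
    gene_id = ids,
    genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    protein_seq = as.character(prot[ids]),
    stringsAsFactors = FALSE
  )
  genes$protein_len <- nchar(genes$protein_seq)
  stopifnot(all(genes$start < genes$end), all(genes$protein_len >= 1L))
  genes <- genes[order(genes$contig_id, genes$start, method = "radix"), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Write gene records to GFF3
#'
#' Inverse of the coordinate conversion in [read_gff3_with_proteins()]:
#' internal 0-based half-open intervals become 1-based inclusive GFF3
#' coordinates.
#'
#' @param genes A gene-record `data.frame` (see [read_gff3_with_proteins()]).
#' @param path Output file path.
#' @param feature_type GFF3 feature type to emit (default `"CDS"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, feature_type = "CDS") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$source <- "cdclminer"
  gr$type <- feature_type
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an HMM hit table
#'
#' Accepts two dialects: the `hmmsearch --tblout` per-sequence table
#' (whitespace-delimited, comment lines starting with `#`, bit score in
#' column 6) and a minimal 4-column TSV
#' (`protein_id`, `model_name`, `bit_score`, `is_partial`) used for
#' synthetic fixtures. The tblout dialect carries no partial flag, so
#' `is_partial` is `FALSE` there; truncated proteins are instead caught
#' downstream by the contig-edge rule in [prune_loci()]. Rows whose score
#' does not parse as a number are skipped with a warning.
#'
#' @param path Path to the hit table.
#' @return A `data.frame` with columns `protein_id`, `model_name`,
#'   `bit_score`, `is_partial`, plus an attribute `n_skipped` counting rows
#'   dropped for unparseable scores. An empty file yields zero rows.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(protein_id = character(), model_name = character(),
                      bit_score = numeric(), is_partial = logical(),
                      stringsAsFactors = FALSE)
  attr(empty, "n_skipped") <- 0L
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (all(nf >= 18L)) {
    protein_id <- vapply(fields, `[[`, "", 1L)
    model_name <- vapply(fields, `[[`, "", 3L)
    score_raw <- vapply(fields, `[[`, "", 6L)
    is_partial <- rep(FALSE, length(fields))
  } else if (all(nf == 4L)) {
    protein_id <- vapply(fields, `[[`, "", 1L)
    model_name <- vapply(fields, `[[`, "", 2L)
    score_raw <- vapply(fields, `[[`, "", 3L)
    is_partial <- toupper(vapply(fields, `[[`, "", 4L)) %in%
      c("TRUE", "T", "1", "YES")
  } else {
    stop("unrecognized hit-table dialect in ", path,
         " (expected hmmsearch --tblout or 4-column TSV)")
  }
  bit_score <- suppressWarnings(as.numeric(score_raw))
  skip <- !is.finite(bit_score)
  if (any(skip)) {
    warning(sum(skip), " hit-table row(s) with unparseable bit score skipped")
  }
  out <- data.frame(protein_id = protein_id[!skip],
                    model_name = model_name[!skip],
                    bit_score = bit_score[!skip],
                    is_partial = is_partial[!skip],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(skip)
  out
}

newick_needs_quote <- function(x) grepl("[\\s()\\[\\]{}:;,'\"]", x, perl = TRUE)

quote_newick_label <- function(x) {
  ifelse(newick_needs_quote(x),
         paste0("'", gsub("'", "''", x), "'"),
         x)
}

#' Serialize a phylogenetic tree to Newick text
#'
#' Writes an `ape::phylo` tree as a Newick string terminated by `";"`.
#' Leaf labels containing Newick metacharacters (whitespace, parentheses,
#' brackets, colon, semicolon, comma, quotes) are single-quoted, with
#' embedded single quotes doubled.
#'
#' @param tree An object of class `phylo` with non-negative branch lengths.
#' @param path Optional file path; when given the text is also written there.
#' @param digits Significant digits for branch lengths (default 12, ample
#'   for round-tripping to within 1e-9).
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 12L) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed")
  }
  ntip <- length(tree$tip.label)
  labels <- quote_newick_label(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt_len <- function(edge_row) {
    if (is.null(tree$edge.length) || is.na(edge_row)) return("")
    paste0(":", format(tree$edge.length[edge_row], digits = digits,
                       scientific = FALSE, trim = TRUE))
  }
  render <- function(node, edge_row) {
    if (node <= ntip) return(paste0(labels[node], fmt_len(edge_row)))
    rows <- kids[[as.character(node)]]
    inner <- vapply(rows, function(r) render(tree$edge[r, 2L], r), "")
    paste0("(", paste(inner, collapse = ","), ")", fmt_len(edge_row))
  }
  root <- ntip + 1L
  text <- paste0(render(root, NA_integer_), ";")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that also strips the single quotes
#' [write_newick()] places around labels containing metacharacters.
#'
#' @param text Newick string, or `NULL` to read from `path`.
#' @param path File path (used when `text` is `NULL`).
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick input")
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tree$tip.label <- unquote(tree$tip.label)
  tree
}

#' Read a FASTQ file (qualities ignored)
#'
#' @param path Path to a FASTQ file (may be gzipped).
#' @return A named character vector of read sequences (names are read IDs).
#' @export
read_fastq <- function(path) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(reads)
  names(out) <- sub("\\s.*$", "", names(reads))
  out
}

#' Write reads to FASTQ with constant qualities
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  quals <- Biostrings::BStringSet(vapply(nchar(reads),
                                         function(n) strrep("I", n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (nucleotide or protein).
#' @param path Output path.
#' @param type `"DNA"` or `"AA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::DNAStringSet(unname(seqs))
       else Biostrings::AAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a FASTA file.
#' @param type `"DNA"` or `"AA"`.
#' @return Named character vector; header text after the first whitespace is
#'   dropped from the names.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
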