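#' Percent identity of two proteins under global alignment
#'
#' Aligns two amino-acid sequences globally (Needleman-Wunsch via
#' [Biostrings::pairwiseAlignment()]) on a 0/1 identity substitution model
#' (match +1, mismatch 0, gap open 10, gap extend 0.5) and computes
#' identity as the number of identical aligned residue pairs divided by a
#' configurable denominator: all alignment columns including terminal gaps
#' (`"alignment_cols"`, default, the conservative reading of a
#' "protein-level ID" threshold), or the shorter sequence length
#' (`"shorter_seq"`).
#'
#' @param a,b Non-empty amino-acid strings.
#' @param denominator `"alignment_cols"` or `"shorter_seq"`.
#' @return A list with `seq_a_id`/`seq_b_id` (names of `a`/`b` if set),
#'   `identity` (fraction in \[0, 1\]), and `aligned_cols` (alignment
#'   columns).
#' @export
pairwise_identity <- function(a, b,
                              denominator = c("alignment_cols", "shorter_seq")) {
  denominator <- match.arg(denominator)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in pairwise_identity")
  if (a == b) {
    n <- nchar(a)
    return(list(seq_a_id = names(a), seq_b_id = names(b),
                identity = 1, aligned_cols = n))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .identity_submat(),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ident <- sum(p == s & p != "-")
  cols <- length(p)
  denom <- if (denominator == "alignment_cols") cols else min(nchar(a), nchar(b))
  list(seq_a_id = names(a), seq_b_id = names(b),
       identity = ident / denom, aligned_cols = cols)
}

.identity_submat_cache <- new.env(parent = emptyenv())

.identity_submat <- function() {
  if (is.null(.identity_submat_cache$mat)) {
    aa <- c(Biostrings::AA_STANDARD, "B", "J", "Z", "X", "U", "O", "*")
    mat <- outer(aa, aa, function(x, y) as.numeric(x == y))
    dimnames(mat) <- list(aa, aa)
    .identity_submat_cache$mat <- mat
  }
  .identity_submat_cache$mat
}

#' Greedy single-pass clustering at an identity threshold
#'
#' CD-HIT-style greedy clustering: sequences are processed in decreasing
#' length order (ties broken by lexicographic id); each sequence joins the
#' first existing cluster (in creation order) whose representative it
#' matches at `>= threshold` identity, otherwise it founds a new cluster
#' with itself as representative. Because representatives are the longest
#' members, a candidate whose length ratio to the representative already
#' caps identity below the threshold is skipped without aligning. A second
#' alignment-free prescreen skips pairs whose shared k-mer count is below
#' what any alignment at `>= threshold` identity must retain (each
#' non-identical alignment column can destroy at most k shared k-mers), so
#' unrelated pairs never pay for a full alignment.
#'
#' @param seqs Named character vector of protein sequences (unique names).
#' @param threshold Identity threshold in (0, 1] (default 0.96).
#' @param denominator Identity denominator, see [pairwise_identity()].
#' @return A `data.frame` with one row per cluster: `cluster_id` (integer,
#'   creation order), `representative_id`, `member_ids` (comma-joined),
#'   `n_members`; plus an attribute `membership`, a named integer vector
#'   mapping every sequence id to its cluster.
#' @export
greedy_cluster <- function(seqs, threshold = 0.96,
                           denominator = c("alignment_cols", "shorter_seq")) {
  denominator <- match.arg(denominator)
  stopifnot(threshold > 0, threshold <= 1, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids, method = "radix")
  kw <- 4L  # prescreen word size
  kmer_counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < kw) return(table(character(0)))
    pos <- seq_len(n - kw + 1L)
    table(substring(s, pos, pos + kw - 1L))
  })
  shared_kmers <- function(ta, tb) {
    common <- intersect(names(ta), names(tb))
    if (length(common) == 0L) return(0L)
    sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
  }
  rep_id <- character(0)
  members <- list()
  membership <- integer(length(seqs))
  names(membership) <- ids
  for (i in ord) {
    id <- ids[i]
    s <- unname(seqs[i])
    placed <- 0L
    for (k in seq_along(rep_id)) {
      rs <- unname(seqs[rep_id[k]])
      lmin <- min(nchar(s), nchar(rs))
      lmax <- max(nchar(s), nchar(rs))
      # identity can't exceed min/max length ratio under either denominator
      if (lmin / lmax < threshold && denominator == "alignment_cols") next
      # any alignment at >= threshold identity over >= lmax columns keeps at
      # least lmax*(1 - kw*(1-threshold)) - kw + 1 intact shared k-mers
      min_shared <- lmax * (1 - kw * (1 - threshold)) - kw + 1
      if (min_shared > 0 &&
          shared_kmers(kmer_counts[[id]], kmer_counts[[rep_id[k]]]) <
            min_shared) next
      if (pairwise_identity(s, rs, denominator)$identity >= threshold) {
        placed <- k
        break
      }
    }
    if (placed == 0L) {
      rep_id <- c(rep_id, id)
      members[[length(members) + 1L]] <- id
      placed <- length(rep_id)
    } else {
      members[[placed]] <- c(members[[placed]], id)
    }
    membership[id] <- placed
  }
  out <- data.frame(
    cluster_id = seq_along(rep_id),
    representative_id = rep_id,
    member_ids = vapply(members, paste, "", collapse = ","),
    n_members = lengths(members),
    stringsAsFactors = FALSE
  )
  attr(out, "membership") <- membership
  out
}

#' Strand-relative gene order of a locus
#'
#' Returns locus genes ordered 5' to 3' on the coding strand: genomic order
#' for `+` loci, reversed genomic order for `-` loci, so the first gene is
#' the transcriptionally upstream one.
#'
#' @param locus_genes `data.frame` of one locus's gene rows.
#' @return The same rows reordered.
#' @export
strand_relative_order <- function(locus_genes) {
  g <- locus_genes[order(locus_genes$start), , drop = FALSE]
  if (g$strand[1L] == "-") g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
  g
}

#' Assign a locus type and per-gene size classes
#'
#' Pairs whose length ratio (shorter/longer) is at least `similar_ratio_min`
#' are "similar-sized" (both genes class `"M"`); otherwise the shorter gene
#' is `"S"` and the longer `"L"`, and the canonical architecture has the
#' small subunit upstream -- a pair whose upstream gene is the larger one is
#' flagged anomalous. Triplets apply the same ratio rule to their extreme
#' lengths: all-similar triplets are `"M"`, otherwise the shortest is `"S"`,
#' the longest `"L"`, and genes within `similar_ratio_min` of the maximum
#' are `"L"`, within it of the minimum `"S"`, else `"M"` (a heuristic
#' generalization, flagged as such in outputs).
#'
#' @param locus_genes One locus's gene rows (2 or 3 genes).
#' @param similar_ratio_min Ratio at or above which two lengths count as
#'   similar (default 0.85; the 365/500 archetype ratio 0.73 must classify
#'   as different).
#' @return A list: `locus_type` (`"S+L pair"`, `"similar-sized pair"`,
#'   `"triplet"`), `size_class` (character vector, strand-relative order),
#'   `gene_id` (ids in strand-relative order), `anomalous_upstream_large`
#'   (logical).
#' @export
assign_locus_type <- function(locus_genes, similar_ratio_min = 0.85) {
  stopifnot(nrow(locus_genes) %in% c(2L, 3L))
  g <- strand_relative_order(locus_genes)
  len <- g$protein_len
  if (nrow(g) == 2L) {
    ratio <- min(len) / max(len)
    if (ratio >= similar_ratio_min) {
      return(list(locus_type = "similar-sized pair",
                  size_class = c("M", "M"), gene_id = g$gene_id,
                  anomalous_upstream_large = FALSE))
    }
    size_class <- ifelse(len == min(len), "S", "L")
    list(locus_type = "S+L pair", size_class = size_class,
         gene_id = g$gene_id,
         anomalous_upstream_large = size_class[1L] == "L")
  } else {
    ratio <- min(len) / max(len)
    if (ratio >= similar_ratio_min) {
      size_class <- c("M", "M", "M")
    } else {
      size_class <- vapply(len, function(l) {
        if (l / max(len) >= similar_ratio_min) "L"
        else if (min(len) / l >= similar_ratio_min) "S"
        else "M"
      }, "")
    }
    list(locus_type = "triplet", size_class = size_class, gene_id = g$gene_id,
         anomalous_upstream_large = FALSE)
  }
}

#' Derive locus architecture patterns from cluster assignments
#'
#' A locus's signature is the strand-relative (5' to 3') tuple of the
#' cluster ids of its genes. Loci are grouped by signature; pattern ids are
#' assigned by decreasing group size, ties broken by lexicographic
#' signature.
#'
#' @param loci A `cdcl_loci` object (pruned; see [prune_loci()]).
#' @param clusters Cluster table from [greedy_cluster()] (its `membership`
#'   attribute must cover every locus gene).
#' @param similar_ratio_min Passed to [assign_locus_type()].
#' @return A `data.frame` with one row per pattern: `pattern_id`,
#'   `signature` (cluster ids joined by `"-"`), `locus_type`, `n_loci`,
#'   `locus_ids` and `genomes` (comma-joined).
#' @export
derive_patterns <- function(loci, clusters, similar_ratio_min = 0.85) {
  genes <- if (inherits(loci, "cdcl_loci")) loci$genes else loci
  membership <- attr(clusters, "membership")
  absent <- setdiff(genes$gene_id, names(membership))
  if (length(absent) > 0L) {
    stop("locus gene(s) absent from all clusters: ",
         paste(absent, collapse = ", "))
  }
  by_locus <- split(genes, genes$locus_id)
  info <- lapply(by_locus, function(g) {
    go <- strand_relative_order(g)
    typ <- assign_locus_type(go, similar_ratio_min)
    list(signature = paste(membership[go$gene_id], collapse = "-"),
         locus_type = typ$locus_type,
         locus_id = g$locus_id[1L], genome_id = g$genome_id[1L])
  })
  sig <- vapply(info, `[[`, "", "signature")
  groups <- split(info, sig)
  n_loci <- vapply(groups, length, integer(1))
  ord <- order(-n_loci, names(groups), method = "radix")
  groups <- groups[ord]
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    grp <- groups[[i]]
    data.frame(
      pattern_id = i,
      signature = grp[[1L]]$signature,
      locus_type = grp[[1L]]$locus_type,
      n_loci = length(grp),
      locus_ids = paste(vapply(grp, `[[`, "", "locus_id"), collapse = ","),
      genomes = paste(unique(vapply(grp, `[[`, "", "genome_id")),
                      collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
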