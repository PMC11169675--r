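#' Filter HMM hits into CDCL candidates
#'
#' Applies the first stage of the discovery funnel: a hit is retained iff
#' its bit score is at or above the cutoff (default 25, the Pfam gathering
#' threshold for the thiol-activated cytolysin model), it is not flagged
#' partial, and its protein length falls inside the sanity window (default
#' 100-700 aa, bracketing the observed 117-674 aa range). Bounds are
#' inclusive.
#'
#' @param hits Hit table `data.frame` (see [read_hit_table()]).
#' @param genes Gene-record `data.frame` (see [read_gff3_with_proteins()]).
#' @param min_bitscore Bit-score cutoff (default 25).
#' @param len_window Length-two numeric, inclusive protein-length window in
#'   amino acids (default `c(100, 700)`).
#' @return A candidate `data.frame`: the matching gene records plus a
#'   `bit_score` column, sorted by (genome_id, contig_id, start).
#' @export
filter_candidates <- function(hits, genes, min_bitscore = 25,
                              len_window = c(100, 700)) {
  unresolved <- setdiff(hits$protein_id, genes$gene_id)
  if (length(unresolved) > 0L) {
    stop("hit protein_id(s) with no matching gene record: ",
         paste(unresolved, collapse = ", "))
  }
  keep <- hits[hits$bit_score >= min_bitscore & !hits$is_partial, , drop = FALSE]
  idx <- match(keep$protein_id, genes$gene_id)
  cand <- genes[idx, , drop = FALSE]
  cand$bit_score <- keep$bit_score
  inwin <- cand$protein_len >= len_window[1L] & cand$protein_len <= len_window[2L]
  cand <- cand[inwin, , drop = FALSE]
  cand <- cand[order(cand$genome_id, cand$contig_id, cand$start,
                     method = "radix"), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Group candidates into adjacent co-oriented runs
#'
#' Finds maximal runs of candidate genes that share a contig and strand and
#' whose consecutive intergenic gaps (`next start - previous end`, internal
#' 0-based half-open coordinates; overlaps count as gap 0) are at most
#' `max_gap`. Runs of length 1 are reported separately as singletons; runs
#' longer than `max_run` are truncated to the first `max_run` genes by
#' coordinate with a warning.
#'
#' @param candidates Candidate `data.frame` from [filter_candidates()].
#' @param max_gap Maximum intergenic gap in bp (default 5000).
#' @param max_run Maximum locus arity (default 3).
#' @return An object of class `cdcl_loci`: a list with `genes` (candidate
#'   rows retained in loci, plus `locus_id` and `locus_pos`), `loci` (one
#'   row per locus: `locus_id`, `genome_id`, `contig_id`, `strand`,
#'   `n_genes`, `gene_ids`, `max_internal_gap`), and `singletons`
#'   (candidate rows not in any locus).
#' @export
group_adjacent <- function(candidates, max_gap = 5000L, max_run = 3L) {
  # runs are detected within each (genome, contig, strand) subset, so an
  # intervening opposite-strand gene does not break a same-strand run
  cand <- candidates[order(candidates$genome_id, candidates$contig_id,
                           candidates$strand, candidates$start,
                           method = "radix"), , drop = FALSE]
  n <- nrow(cand)
  run_id <- integer(n)
  if (n > 0L) {
    run_id[1L] <- 1L
    if (n > 1L) {
      same <- cand$genome_id[-1L] == cand$genome_id[-n] &
        cand$contig_id[-1L] == cand$contig_id[-n] &
        cand$strand[-1L] == cand$strand[-n]
      gap <- pmax(cand$start[-1L] - cand$end[-n], 0L)
      new_run <- !(same & gap <= max_gap)
      run_id[-1L] <- 1L + cumsum(new_run)
    }
  }
  runs <- split(seq_len(n), run_id)
  truncated <- FALSE
  locus_rows <- list()
  singleton_rows <- integer(0)
  for (r in runs) {
    if (length(r) == 1L) {
      singleton_rows <- c(singleton_rows, r)
    } else {
      if (length(r) > max_run) {
        truncated <- TRUE
        r <- r[seq_len(max_run)]
      }
      locus_rows[[length(locus_rows) + 1L]] <- r
    }
  }
  if (truncated) {
    warning("run(s) longer than max_run = ", max_run,
            " truncated to the first ", max_run, " genes by coordinate")
  }
  genes_list <- lapply(seq_along(locus_rows), function(i) {
    g <- cand[locus_rows[[i]], , drop = FALSE]
    g$locus_id <- sprintf("%s|%s|%d", g$genome_id[1L], g$contig_id[1L],
                          g$start[1L])
    g$locus_pos <- seq_len(nrow(g))
    g
  })
  genes <- if (length(genes_list)) do.call(rbind, genes_list) else
    cbind(cand[0, , drop = FALSE],
          data.frame(locus_id = character(), locus_pos = integer()))
  rownames(genes) <- NULL
  singletons <- cand[singleton_rows, , drop = FALSE]
  rownames(singletons) <- NULL
  structure(list(genes = genes,
                 loci = summarize_loci(genes),
                 singletons = singletons),
            class = "cdcl_loci")
}

summarize_loci <- function(genes) {
  if (nrow(genes) == 0L) {
    return(data.frame(locus_id = character(), genome_id = character(),
                      contig_id = character(), strand = character(),
                      n_genes = integer(), gene_ids = character(),
                      max_internal_gap = integer(), stringsAsFactors = FALSE))
  }
  by_locus <- split(genes, genes$locus_id)
  out <- do.call(rbind, lapply(by_locus, function(g) {
    g <- g[order(g$start), , drop = FALSE]
    gaps <- if (nrow(g) > 1L) pmax(g$start[-1L] - g$end[-nrow(g)], 0L) else 0L
    data.frame(locus_id = g$locus_id[1L], genome_id = g$genome_id[1L],
               contig_id = g$contig_id[1L], strand = g$strand[1L],
               n_genes = nrow(g),
               gene_ids = paste(g$gene_id, collapse = ","),
               max_internal_gap = max(gaps), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$genome_id, out$contig_id,
                   vapply(by_locus, function(g) min(g$start), integer(1))[
                     match(out$locus_id, names(by_locus))],
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.cdcl_loci <- function(x, ...) {
  cat("CDCL loci:", nrow(x$loci), "loci (",
      sum(x$loci$n_genes == 2L), "pairs,", sum(x$loci$n_genes == 3L),
      "triplets ),", nrow(x$singletons), "singletons\n")
  invisible(x)
}

#' Prune loci by signal-peptide class and contig-edge defects
#'
#' Applies the orphan and defect rules: (1) genes whose signal category is
#' neither `SpII` nor `RescuedSpII` are removed from their locus; (2) loci
#' reduced below 2 genes are dropped (the surviving gene is orphaned);
#' (3) loci containing a gene whose interval touches a contig boundary
#' (`start == 0` or `end == contig length`) are dropped entirely.
#'
#' @param loci A `cdcl_loci` object whose `genes` carry a `signal_category`
#'   column (see [classify_signals()]).
#' @param contigs Optional `data.frame` with columns `contig_id` and
#'   `length`; required for the contig-edge rule (skipped when `NULL`).
#' @return A pruned `cdcl_loci` object; `singletons` additionally collects
#'   genes orphaned by rule (2).
#' @export
prune_loci <- function(loci, contigs = NULL) {
  stopifnot(inherits(loci, "cdcl_loci"),
            "signal_category" %in% names(loci$genes))
  genes <- loci$genes
  keep_signal <- genes$signal_category %in% c("SpII", "RescuedSpII")
  genes2 <- genes[keep_signal, , drop = FALSE]
  counts <- table(genes2$locus_id)
  ok_size <- names(counts)[counts >= 2L]
  orphaned <- genes2[!(genes2$locus_id %in% ok_size), , drop = FALSE]
  genes2 <- genes2[genes2$locus_id %in% ok_size, , drop = FALSE]
  if (!is.null(contigs)) {
    clen <- contigs$length[match(genes2$contig_id, contigs$contig_id)]
    if (anyNA(clen)) stop("contig length missing for: ",
                          paste(unique(genes2$contig_id[is.na(clen)]),
                                collapse = ", "))
    at_edge <- genes2$start == 0L | genes2$end == clen
    bad_loci <- unique(genes2$locus_id[at_edge])
    genes2 <- genes2[!(genes2$locus_id %in% bad_loci), , drop = FALSE]
  }
  # renumber within-locus positions after removals
  genes2 <- genes2[order(genes2$genome_id, genes2$contig_id, genes2$start,
                         method = "radix"), , drop = FALSE]
  genes2$locus_pos <- stats::ave(seq_len(nrow(genes2)), genes2$locus_id,
                                 FUN = seq_along)
  rownames(genes2) <- NULL
  sing <- loci$singletons
  if (nrow(orphaned) > 0L) {
    orphaned$locus_id <- NULL
    orphaned$locus_pos <- NULL
    common <- intersect(names(sing), names(orphaned))
    sing <- rbind(sing[, common, drop = FALSE], orphaned[, common, drop = FALSE])
  }
  structure(list(genes = genes2, loci = summarize_loci(genes2),
                 singletons = sing),
            class = "cdcl_loci")
}

#' Run the full locus-discovery funnel
#'
#' Convenience wrapper chaining [filter_candidates()], signal-peptide
#' classification, [group_adjacent()], and [prune_loci()], recording the
#' gene count surviving each stage.
#'
#' @param genes Gene records (see [read_gff3_with_proteins()]).
#' @param hits Hit table (see [read_hit_table()]).
#' @param contigs Optional contig table (`contig_id`, `length`) for the
#'   contig-edge rule.
#' @param min_bitscore,len_window,max_gap,max_run Stage parameters; see the
#'   individual functions.
#' @param signal_table Optional precomputed signal-call `data.frame`
#'   (`protein_id`, `category`) overriding the built-in heuristic, e.g. an
#'   ingested LipoP result table. Proteins absent from the table get the
#'   built-in call.
#' @return A list: `loci` (pruned `cdcl_loci`), `candidates` (post-filter
#'   candidate table with signal calls), and `funnel` (named integer vector
#'   of gene counts per stage).
#' @export
mine_loci <- function(genes, hits, contigs = NULL,
                      min_bitscore = 25, len_window = c(100, 700),
                      max_gap = 5000L, max_run = 3L,
                      signal_table = NULL) {
  cand <- filter_candidates(hits, genes, min_bitscore = min_bitscore,
                            len_window = len_window)
  calls <- classify_signals(cand$protein_seq)
  cand$signal_category <- calls$category
  cand$lipobox_cys_pos <- calls$lipobox_cys_pos
  if (!is.null(signal_table)) {
    idx <- match(cand$gene_id, signal_table$protein_id)
    hit <- !is.na(idx)
    cand$signal_category[hit] <- signal_table$category[idx[hit]]
  }
  grouped <- group_adjacent(cand, max_gap = max_gap, max_run = max_run)
  pruned <- prune_loci(grouped, contigs = contigs)
  funnel <- c(hits = nrow(hits),
              candidates = nrow(cand),
              in_runs = nrow(grouped$genes),
              retained = nrow(pruned$genes),
              loci = nrow(pruned$loci))
  list(loci = pruned, candidates = cand, funnel = funnel)
}

#' Write a locus table to TSV
#'
#' One row per locus with per-gene fields joined by commas, mirroring the
#' `mine` CLI output contract.
#'
#' @param result Result list from [mine_loci()] (or a `cdcl_loci` object).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_loci_tsv <- function(result, path) {
  loci <- if (inherits(result, "cdcl_loci")) result else result$loci
  g <- loci$genes
  by_locus <- split(g, g$locus_id)
  rows <- do.call(rbind, lapply(by_locus, function(x) {
    x <- x[order(x$start), , drop = FALSE]
    data.frame(genome = x$genome_id[1L], contig = x$contig_id[1L],
               locus_id = x$locus_id[1L],
               gene_ids = paste(x$gene_id, collapse = ","),
               strands = paste(x$strand, collapse = ","),
               starts = paste(x$start, collapse = ","),
               ends = paste(x$end, collapse = ","),
               lengths_aa = paste(x$protein_len, collapse = ","),
               signal_categories = paste(x$signal_category, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(genome = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
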