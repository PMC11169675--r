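.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build a k-mer index over reference sequences
#'
#' @param refs Named character vector of reference nucleotide sequences.
#' @param k K-mer length (default 21; must be at least 11). References
#'   shorter than `k` are excluded with a warning.
#' @return An object of class `kmer_index` (environment-backed) used by
#'   [map_reads()].
#' @export
build_kmer_index <- function(refs, k = 21L) {
  stopifnot(k >= 11L, !is.null(names(refs)))
  too_short <- nchar(refs) < k
  if (any(too_short)) {
    warning("reference(s) shorter than k excluded: ",
            paste(names(refs)[too_short], collapse = ", "))
    refs <- refs[!too_short]
  }
  if (length(refs) == 0L) stop("no references of length >= k")
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (ri in seq_along(refs)) {
    s <- refs[[ri]]
    npos <- nchar(s) - k + 1L
    pos <- seq_len(npos)
    kmers <- substring(s, pos, pos + k - 1L)
    sp <- split(pos, kmers)
    for (km in names(sp)) {
      prev <- env[[km]]
      entry <- cbind(ref = ri, pos = sp[[km]])
      env[[km]] <- if (is.null(prev)) entry else rbind(prev, entry)
    }
  }
  structure(list(env = env, k = k, ref_ids = names(refs),
                 ref_len = unname(nchar(refs)), refs = unname(refs)),
            class = "kmer_index")
}

.count_matches <- function(a, b) {
  sum(charToRaw(a) == charToRaw(b))
}

#' Competitively map reads to references (best match, single-counted)
#'
#' Seed-and-extend mapping with best-match ambiguity resolution: each read
#' (both its forward sequence and reverse complement) is seeded by exact
#' k-mer lookups against the reference index, every seed is extended
#' ungapped across the full read length, and the read is assigned to the
#' single candidate with the most matching bases, provided
#' `matches / aln_len >= min_identity`. Ties are broken by lowest reference
#' index, then leftmost reference position, then forward before reverse
#' orientation, so each read is counted exactly once. Indels are not
#' modeled.
#'
#' @param reads Named character vector of read sequences, or a FASTQ path
#'   (read via [read_fastq()]).
#' @param refs Named character vector of reference sequences, or a
#'   `kmer_index` from [build_kmer_index()].
#' @param k Seed k-mer length (default 21; ignored when `refs` is already
#'   an index).
#' @param min_identity Minimum `matches / aln_len` to accept an assignment
#'   (default 0.95).
#' @return A `data.frame` with one row per read: `read_id`, `ref_id` (`NA`
#'   when unassigned), `ref_start` (0-based), `matches`, `aln_len`,
#'   `strand` (`"+"`/`"-"`/`NA`).
#' @export
map_reads <- function(reads, refs, k = 21L, min_identity = 0.95) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  index <- if (inherits(refs, "kmer_index")) refs else build_kmer_index(refs, k)
  k <- index$k
  env <- index$env
  n <- length(reads)
  out_ref <- character(n)
  out_start <- integer(n)
  out_matches <- integer(n)
  out_alen <- integer(n)
  out_strand <- character(n)
  rc <- .revcomp(reads)
  for (ridx in seq_len(n)) {
    best <- NULL  # c(ref, start0, matches, aln_len, strand_code)
    for (ori in 1:2) {
      seq <- if (ori == 1L) reads[[ridx]] else rc[[ridx]]
      len <- nchar(seq)
      if (len < k) next
      npos <- len - k + 1L
      kpos <- seq_len(npos)
      kmers <- substring(seq, kpos, kpos + k - 1L)
      cand <- NULL
      for (ki in kpos) {
        hit <- env[[kmers[ki]]]
        if (is.null(hit)) next
        cand <- rbind(cand, cbind(ref = hit[, "ref"],
                                  start0 = (hit[, "pos"] - 1L) - (ki - 1L)))
      }
      if (is.null(cand)) next
      cand <- unique(cand)
      for (ci in seq_len(nrow(cand))) {
        ref_i <- cand[ci, "ref"]
        start0 <- cand[ci, "start0"]
        ref_len <- index$ref_len[ref_i]
        a0 <- max(0L, start0)
        a1 <- min(ref_len, start0 + len)
        aln_len <- a1 - a0
        if (aln_len < k) next
        ref_seg <- substr(index$refs[ref_i], a0 + 1L, a1)
        read_seg <- substr(seq, a0 - start0 + 1L, a1 - start0)
        matches <- .count_matches(ref_seg, read_seg)
        if (matches / aln_len < min_identity) next
        cur <- c(ref_i, a0, matches, aln_len, ori)
        if (is.null(best) ||
            matches > best[3L] ||
            (matches == best[3L] &&
             (cur[1L] < best[1L] ||
              (cur[1L] == best[1L] &&
               (cur[2L] < best[2L] ||
                (cur[2L] == best[2L] && cur[5L] < best[5L])))))) {
          best <- cur
        }
      }
    }
    if (is.null(best)) {
      out_ref[ridx] <- NA_character_
      out_start[ridx] <- NA_integer_
      out_matches[ridx] <- 0L
      out_alen[ridx] <- 0L
      out_strand[ridx] <- NA_character_
    } else {
      out_ref[ridx] <- index$ref_ids[best[1L]]
      out_start[ridx] <- best[2L]
      out_matches[ridx] <- best[3L]
      out_alen[ridx] <- best[4L]
      out_strand[ridx] <- c("+", "-")[best[5L]]
    }
  }
  data.frame(read_id = if (is.null(names(reads)))
               paste0("read", seq_len(n)) else names(reads),
             ref_id = out_ref, ref_start = out_start,
             matches = out_matches, aln_len = out_alen,
             strand = out_strand, stringsAsFactors = FALSE)
}

#' Per-reference coverage statistics
#'
#' Accumulates per-base depth over each assignment's interval
#' `[ref_start, ref_start + aln_len)` and reduces to breadth (fraction of
#' reference positions with depth >= 1), read count, and mean depth (total
#' aligned bases divided by the full reference length, uncovered positions
#' included).
#'
#' @param assignments Assignment `data.frame` from [map_reads()].
#' @param ref_id Reference to summarize.
#' @param ref_len Reference length in bp.
#' @return A list with `ref_id`, `breadth`, `n_reads`, `mean_depth`, and
#'   `depth` (the per-base integer depth vector).
#' @export
coverage_stats <- function(assignments, ref_id, ref_len) {
  stopifnot(ref_len >= 1L)
  a <- assignments[!is.na(assignments$ref_id) &
                     assignments$ref_id == ref_id, , drop = FALSE]
  depth <- integer(ref_len)
  truncated <- FALSE
  for (i in seq_len(nrow(a))) {
    s <- a$ref_start[i] + 1L
    e <- a$ref_start[i] + a$aln_len[i]
    if (e > ref_len) {
      truncated <- TRUE
      e <- ref_len
    }
    if (s < 1L) s <- 1L
    if (s <= e) depth[s:e] <- depth[s:e] + 1L
  }
  if (truncated) {
    warning("assignment interval(s) beyond reference end truncated")
  }
  list(ref_id = ref_id,
       breadth = mean(depth >= 1L),
       n_reads = nrow(a),
       mean_depth = sum(depth) / ref_len,
       depth = depth)
}

#' Presence call from coverage statistics
#'
#' A reference locus is called present when all three thresholds are met
#' (each inclusive): breadth of coverage at least `min_breadth`, at least
#' `min_reads` assigned reads, and mean depth at least `min_depth`
#' (defaults 0.75 / 20 / 5, the published criterion).
#'
#' @param stats Coverage statistics from [coverage_stats()].
#' @param min_breadth Minimum breadth (default 0.75).
#' @param min_reads Minimum assigned-read count (default 20).
#' @param min_depth Minimum mean depth (default 5.0).
#' @return A list with `ref_id`, `present` (logical), `stats`, and
#'   `thresholds`.
#' @export
call_presence <- function(stats, min_breadth = 0.75, min_reads = 20L,
                          min_depth = 5.0) {
  present <- stats$breadth >= min_breadth &&
    stats$n_reads >= min_reads &&
    stats$mean_depth >= min_depth
  list(ref_id = stats$ref_id, present = present,
       stats = stats[c("breadth", "n_reads", "mean_depth")],
       thresholds = c(min_breadth = min_breadth, min_reads = min_reads,
                      min_depth = min_depth))
}

.round_half_away <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-pattern prevalence across metagenomic samples
#'
#' A pattern counts as detected in a sample when any of its reference loci
#' is present there. Percentages are reported to one decimal place, rounding
#' half away from zero.
#'
#' @param calls A `data.frame` with columns `sample`, `pattern`, and
#'   `present` (logical); every sample must be evaluated for every pattern.
#' @return A `data.frame` with one row per pattern: `pattern`, `n_detected`,
#'   `n_samples`, `percent`.
#' @export
prevalence_report <- function(calls) {
  stopifnot(all(c("sample", "pattern", "present") %in% names(calls)))
  n_samples <- length(unique(calls$sample))
  if (n_samples == 0L) stop("no samples in prevalence_report")
  by_pat <- split(calls, calls$pattern)
  out <- do.call(rbind, lapply(by_pat, function(x) {
    det <- tapply(x$present, x$sample, any)
    n_detected <- sum(det)
    data.frame(pattern = x$pattern[1L],
               n_detected = n_detected,
               n_samples = n_samples,
               percent = .round_half_away(100 * n_detected / n_samples, 1L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
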