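# Kyte-Doolittle hydropathy scale
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.kd_mean <- function(residues) {
  v <- .KD[residues]
  if (anyNA(v)) v[is.na(v)] <- 0  # non-standard residues treated as neutral
  mean(v)
}

#' Scan for the [SA]C rescue motif in the N-terminus
#'
#' Second-pass reclassification of proteins that miss the full lipobox
#' heuristic: returns `TRUE` when the dipeptide `SC` or `AC` occurs entirely
#' within the first 35 residues, i.e. the cysteine sits at 0-based index 34
#' or earlier.
#'
#' @param protein_seq Amino-acid string (vectorized).
#' @return Logical vector.
#' @export
rescue_spii <- function(protein_seq) {
  head35 <- substr(protein_seq, 1L, 35L)
  grepl("[SA]C", head35)
}

#' Classify the signal peptide of a protein
#'
#' Heuristic lipoprotein (SpII) signal-peptide call. A protein is `SpII`
#' when it has a lipobox `[LVI][ASTVI][GAS]C` whose cysteine lies at 0-based
#' index 10-34, the 8 residues preceding the lipobox have mean
#' Kyte-Doolittle hydropathy > 0 (the hydrophobic h-region), and at least
#' one of residues at 0-based positions 1-7 is K or R (the positively
#' charged n-region). Proteins failing that but carrying the `[SA]C` rescue
#' motif in the first 35 residues (see [rescue_spii()]) are `RescuedSpII`.
#' Remaining proteins are `SpI` when an A-x-A motif starts at 0-based index
#' 15-30 preceded by a hydrophobic stretch (mean hydropathy of the 8
#' preceding residues > 0), else `None`. Only the SpII/RescuedSpII boundary
#' matters downstream; SpI is reported for tally parity.
#'
#' @param protein_seq A single amino-acid string.
#' @return A list with `category` (one of `"SpII"`, `"RescuedSpII"`,
#'   `"SpI"`, `"None"`), `lipobox_cys_pos` (0-based index of the lipobox or
#'   rescue cysteine; `NA` otherwise), and `evidence` (short text tag).
#' @export
classify_signal_peptide <- function(protein_seq) {
  stopifnot(length(protein_seq) == 1L)
  if (nchar(protein_seq) < 20L) {
    return(list(category = "None", lipobox_cys_pos = NA_integer_,
                evidence = "too_short"))
  }
  chars <- strsplit(protein_seq, "")[[1]]
  n <- length(chars)

  # lipobox scan: cysteine (match start + 3, 0-based) must lie in [10, 34]
  m <- gregexpr("(?=([LVI][ASTVI][GAS]C))", protein_seq, perl = TRUE)[[1]]
  starts1 <- as.integer(m)  # 1-based match starts (lookahead allows overlaps)
  if (starts1[1L] != -1L) {
    for (s1 in starts1) {
      cys0 <- (s1 - 1L) + 3L            # 0-based cysteine index
      if (cys0 < 10L || cys0 > 34L) next
      lip_start1 <- s1                   # 1-based lipobox start
      if (lip_start1 - 8L < 1L) next     # need 8 residues of h-region
      hreg <- chars[(lip_start1 - 8L):(lip_start1 - 1L)]
      if (.kd_mean(hreg) <= 0) next
      nreg <- chars[2L:min(8L, n)]       # 0-based positions 1-7
      if (!any(nreg %in% c("K", "R"))) next
      return(list(category = "SpII", lipobox_cys_pos = cys0,
                  evidence = "lipobox"))
    }
  }

  if (rescue_spii(protein_seq)) {
    r <- regexpr("[SA]C", substr(protein_seq, 1L, 35L))
    cys0 <- as.integer(r)                # 1-based match start == 0-based C idx
    return(list(category = "RescuedSpII", lipobox_cys_pos = cys0,
                evidence = "rescue_[SA]C"))
  }

  # SpI fallback: A-x-A starting at 0-based 15-30 with hydrophobic run before
  ma <- gregexpr("(?=(A.A))", protein_seq, perl = TRUE)[[1]]
  if (ma[1L] != -1L) {
    for (s1 in as.integer(ma)) {
      idx0 <- s1 - 1L
      if (idx0 < 15L || idx0 > 30L) next
      if (s1 - 8L < 1L) next
      hreg <- chars[(s1 - 8L):(s1 - 1L)]
      if (.kd_mean(hreg) <= 0) next
      return(list(category = "SpI", lipobox_cys_pos = NA_integer_,
                  evidence = "AxA"))
    }
  }
  list(category = "None", lipobox_cys_pos = NA_integer_, evidence = "none")
}

#' Classify signal peptides for a vector of proteins
#'
#' @param protein_seqs Character vector of amino-acid strings.
#' @return A `data.frame` with columns `category`, `lipobox_cys_pos`,
#'   `evidence`, one row per input sequence.
#' @export
classify_signals <- function(protein_seqs) {
  calls <- lapply(protein_seqs, classify_signal_peptide)
  data.frame(
    category = vapply(calls, `[[`, "", "category"),
    lipobox_cys_pos = vapply(calls, function(x) as.integer(x$lipobox_cys_pos),
                             integer(1)),
    evidence = vapply(calls, `[[`, "", "evidence"),
    stringsAsFactors = FALSE
  )
}
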