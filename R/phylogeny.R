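#' Identity-based distance matrix
#'
#' Builds a symmetric distance matrix over a set of sequences with
#' `d[i, j] = 1 - pairwise_identity(i, j)`.
#'
#' @param representatives Named character vector of protein sequences
#'   (unique names; at least 2).
#' @param denominator Identity denominator, see [pairwise_identity()].
#' @return A symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
distance_matrix <- function(representatives,
                            denominator = c("alignment_cols", "shorter_seq")) {
  denominator <- match.arg(denominator)
  n <- length(representatives)
  stopifnot(n >= 2L, !is.null(names(representatives)))
  if (anyDuplicated(names(representatives))) {
    stop("duplicate sequence labels in distance_matrix")
  }
  labels <- names(representatives)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- pairwise_identity(representatives[[i]], representatives[[j]],
                               denominator)$identity
      d[i, j] <- d[j, i] <- 1 - pid
    }
  }
  d
}

#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Standard Saitou-Nei neighbor joining on a distance matrix. Runs are
#' bit-reproducible: ties in the Q criterion are broken by the smallest
#' (i, j) index pair (row-major over the current matrix), and negative
#' branch-length estimates are clamped to 0 with a single warning. A
#' two-taxon matrix returns a single split with half the distance on each
#' branch.
#'
#' @param dm Symmetric numeric distance matrix with labels as dimnames and
#'   finite non-negative entries (e.g. from [distance_matrix()]).
#' @return An unrooted `ape::phylo` tree whose tip labels equal the matrix
#'   labels.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (!all(is.finite(dm))) stop("non-finite distances in nj_tree")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(dm)))
  n <- nrow(dm)
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) {
      clamped <<- TRUE
      return(0)
    }
    x
  }
  if (n == 2L) {
    half <- dm[1L, 2L] / 2
    txt <- sprintf("(%s:%s,%s:%s);",
                   quote_newick_label(labels[1L]), fmt(half),
                   quote_newick_label(labels[2L]), fmt(half))
    return(read_newick(text = txt))
  }
  # active nodes carried as Newick substrings
  node <- quote_newick_label(labels)
  D <- dm
  while (length(node) > 3L) {
    r <- length(node)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # smallest (i, j), i < j, row-major tie-break
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        if (Q[i, j] < qmin) {
          qmin <- Q[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    merged <- sprintf("(%s:%s,%s:%s)", node[i], fmt(li), node[j], fmt(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dnew <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                  c(dk[keep], 0))
    node <- c(node[keep], merged)
    D <- Dnew
  }
  # join the final three nodes at an unrooted trifurcation
  l1 <- clamp((D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2)
  l2 <- clamp((D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2)
  l3 <- clamp((D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[1L], fmt(l1), node[2L], fmt(l2), node[3L], fmt(l3))
  if (clamped) warning("negative branch length estimate(s) clamped to 0")
  read_newick(text = txt)
}
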