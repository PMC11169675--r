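test_that("pairwise identity matches frozen and oracle values and is symmetric", {
  expect_equal(pairwise_identity("PEPTIDE", "PEPTIDE")$identity, 1.0)
  expect_equal(pairwise_identity("AAAA", "TTTT")$identity, 0.0)
  # single gapless optimum: 8 identical columns over 9
  expect_equal(pairwise_identity("ACDEFGHIK", "ACDEFGHIR")$identity, 8 / 9)

  expect_error(pairwise_identity("", "PEPTIDE"), "empty")

  # symmetry and agreement with the ungapped oracle on close mutants, where
  # gap costs guarantee the optimal alignment is gapless
  set.seed(11)
  for (i in 1:8) {
    a <- random_protein(150L)
    b <- mutate_sequence(a, 0.94, seed = i)
    ab <- pairwise_identity(a, b)$identity
    ba <- pairwise_identity(b, a)$identity
    expect_equal(ab, ba, tolerance = 1e-12)
    expect_equal(ab, hamming_identity(a, b))
  }
})

test_that("identity denominator switch changes the normalization, not the matches", {
  a <- strrep("MKLV", 25L)          # 100 aa
  b <- paste0(a, strrep("Q", 25L))  # 125 aa; terminal gap columns
  cols <- pairwise_identity(a, b)$identity          # 100 / 125
  short <- pairwise_identity(a, b, denominator = "shorter_seq")$identity
  expect_equal(cols, 100 / 125)
  expect_equal(short, 1.0)
})

test_that("greedy clustering honors the threshold, creation order, and exact-match limit", {
  s <- random_protein(120L)
  two_same <- c(a = s, b = s)
  cl <- greedy_cluster(two_same, 0.96)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 2L)

  set.seed(3)
  base <- random_protein(200L)
  far <- mutate_sequence(base, 0.90, seed = 4)
  expect_equal(pairwise_identity(base, far)$identity, 0.90)  # oracle-backed
  cl2 <- greedy_cluster(c(x = base, y = far), 0.96)
  expect_equal(nrow(cl2), 2L)

  three <- c(p = random_protein(100L), q = random_protein(100L),
             r = random_protein(100L))
  cl3 <- greedy_cluster(three, threshold = 1.0)
  expect_equal(nrow(cl3), 3L)
  # threshold 1.0 equals grouping by string equality
  dup <- c(three, p2 = unname(three["p"]))
  cl4 <- greedy_cluster(dup, threshold = 1.0)
  member <- attr(cl4, "membership")
  expect_equal(unname(member["p"]), unname(member["p2"]))
  expect_equal(nrow(cl4), 3L)
})

test_that("every cluster member matches its representative at or above threshold", {
  set.seed(21)
  seqs <- character(0)
  for (fam in 1:3) {
    base <- random_protein(365L)
    fam_seqs <- c(base, vapply(1:4, function(i)
      mutate_sequence(base, 0.98, seed = fam * 100L + i), ""))
    names(fam_seqs) <- sprintf("f%d_s%d", fam, seq_along(fam_seqs))
    seqs <- c(seqs, fam_seqs)
  }
  cl <- greedy_cluster(seqs, 0.96)
  member <- attr(cl, "membership")
  # partition
  expect_setequal(names(member), names(seqs))
  expect_equal(sum(cl$n_members), length(seqs))
  # recomputed member-to-representative identity
  for (k in seq_len(nrow(cl))) {
    ids <- strsplit(cl$member_ids[k], ",")[[1L]]
    for (id in ids) {
      expect_gte(pairwise_identity(seqs[[id]],
                                   seqs[[cl$representative_id[k]]])$identity,
                 0.96)
    }
  }
})

test_that("locus typing follows the size-ratio rule in strand-relative order", {
  mk <- function(lens, strand) {
    n <- length(lens)
    starts <- seq(0L, by = 2000L, length.out = n)
    data.frame(gene_id = paste0("g", seq_len(n)), genome_id = "G",
               contig_id = "c", start = starts, end = starts + 1500L,
               strand = strand, protein_seq = strrep("A", lens),
               protein_len = as.integer(lens), stringsAsFactors = FALSE)
  }
  # archetype small+large pair: 365/500 = 0.73 < 0.85
  t1 <- assign_locus_type(mk(c(365L, 500L), "+"))
  expect_equal(t1$locus_type, "S+L pair")
  expect_equal(t1$size_class, c("S", "L"))
  expect_false(t1$anomalous_upstream_large)

  # similar-sized pair: 336/360 = 0.93
  t2 <- assign_locus_type(mk(c(336L, 360L), "+"))
  expect_equal(t2$locus_type, "similar-sized pair")
  expect_equal(t2$size_class, c("M", "M"))

  # minus strand: genomic order (500, 365) reads as upstream-small
  t3 <- assign_locus_type(mk(c(500L, 365L), "-"))
  expect_equal(t3$size_class, c("S", "L"))
  expect_equal(t3$gene_id, c("g2", "g1"))
  expect_false(t3$anomalous_upstream_large)

  # upstream-larger pair is flagged anomalous
  t4 <- assign_locus_type(mk(c(500L, 365L), "+"))
  expect_true(t4$anomalous_upstream_large)

  t5 <- assign_locus_type(mk(c(365L, 380L, 500L), "+"))
  expect_equal(t5$locus_type, "triplet")
  expect_equal(length(t5$size_class), 3L)
})

test_that("patterns group by strand-relative signature with size-then-signature numbering", {
  mk_locus <- function(locus_id, cluster_of_gene, strand = "+") {
    n <- length(cluster_of_gene)
    starts <- seq(0L, by = 2000L, length.out = n)
    data.frame(gene_id = names(cluster_of_gene), genome_id = "G",
               contig_id = "c", start = starts, end = starts + 1200L,
               strand = strand, protein_seq = strrep("A", 365L),
               protein_len = 365L, locus_id = locus_id,
               locus_pos = seq_len(n), stringsAsFactors = FALSE)
  }
  genes <- rbind(
    mk_locus("L1", c(a1 = 7L, a2 = 12L)),
    mk_locus("L2", c(b1 = 7L, b2 = 12L)),
    mk_locus("L3", c(c1 = 12L, c2 = 7L)))   # reversed order: distinct pattern
  membership <- c(a1 = 7L, a2 = 12L, b1 = 7L, b2 = 12L, c1 = 12L, c2 = 7L)
  clusters <- data.frame(cluster_id = c(7L, 12L),
                         representative_id = c("a1", "a2"),
                         member_ids = c("a1,b1,c2", "a2,b2,c1"),
                         n_members = c(3L, 3L), stringsAsFactors = FALSE)
  attr(clusters, "membership") <- membership
  pat <- derive_patterns(genes, clusters)
  expect_equal(nrow(pat), 2L)
  expect_equal(pat$pattern_id, c(1L, 2L))
  expect_equal(pat$n_loci, c(2L, 1L))       # larger group numbered first
  expect_equal(pat$signature, c("7-12", "12-7"))

  # a minus-strand locus with reversed genomic order joins the 7-12 pattern
  genes2 <- rbind(genes, mk_locus("L4", c(d1 = 12L, d2 = 7L), strand = "-"))
  attr(clusters, "membership") <- c(membership, d1 = 12L, d2 = 7L)
  pat2 <- derive_patterns(genes2, clusters)
  expect_equal(pat2$n_loci[pat2$signature == "7-12"], 3L)

  # input order invariance (membership identical, ids aside)
  shuffled <- genes2[rev(seq_len(nrow(genes2))), ]
  pat3 <- derive_patterns(shuffled, clusters)
  expect_equal(pat3[order(pat3$signature), c("signature", "n_loci")],
               pat2[order(pat2$signature), c("signature", "n_loci")])

  # gene missing from every cluster is a hard error
  genes3 <- rbind(genes, mk_locus("L9", c(zz = 1L)))
  expect_error(derive_patterns(genes3, clusters), "zz")
})
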