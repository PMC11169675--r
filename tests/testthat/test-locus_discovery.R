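make_genes <- function(starts, ends, strands, contig = "c1",
                       genome = "G1", prot_len = 365L) {
  n <- length(starts)
  data.frame(
    gene_id = sprintf("%s_%s_g%d", genome, contig, seq_len(n)),
    genome_id = genome, contig_id = contig,
    start = as.integer(starts), end = as.integer(ends),
    strand = rep_len(strands, n),
    protein_seq = vapply(rep_len(prot_len, n), function(l)
      paste0("MKK", strrep("L", 10L), "LAGC", strrep("Q", l - 17L)), ""),
    protein_len = rep_len(as.integer(prot_len), n),
    stringsAsFactors = FALSE)
}

make_hits <- function(genes, score = 80, partial = FALSE) {
  data.frame(protein_id = genes$gene_id, model_name = "Thiol_cytolysin",
             bit_score = rep_len(score, nrow(genes)),
             is_partial = rep_len(partial, nrow(genes)),
             stringsAsFactors = FALSE)
}

test_that("candidate filter applies inclusive score cutoff, partial flag, and length window", {
  genes <- make_genes(c(100, 2000, 4000, 6000), c(1200, 3100, 5100, 7100),
                      "+", prot_len = c(365L, 365L, 80L, 365L))
  hits <- make_hits(genes)
  hits$bit_score <- c(25.0, 24.9, 80, 80)
  hits$is_partial <- c(FALSE, FALSE, FALSE, TRUE)
  out <- filter_candidates(hits, genes)
  # gene 1: boundary score retained; gene 2: below cutoff; gene 3: too short;
  # gene 4: partial
  expect_equal(out$gene_id, genes$gene_id[1L])
  expect_equal(out$bit_score, 25.0)

  bad <- make_hits(data.frame(gene_id = "ghost"))
  expect_error(filter_candidates(bad, genes), "ghost")
})

test_that("adjacency grouping respects contig, strand, and gap; singletons split off", {
  # two same-strand genes 400 bp apart -> one pair
  g <- make_genes(c(1000, 2498), c(2098, 4000), "+")
  g$bit_score <- 80
  g$signal_category <- "SpII"
  grp <- group_adjacent(g, max_gap = 5000L)
  expect_equal(nrow(grp$loci), 1L)
  expect_equal(grp$loci$n_genes, 2L)
  expect_equal(grp$loci$max_internal_gap, 400L)

  # opposite strands, tiny gap -> no loci, two singletons
  g2 <- make_genes(c(1000, 2148), c(2098, 3300), c("+", "-"))
  g2$bit_score <- 80
  grp2 <- group_adjacent(g2)
  expect_equal(nrow(grp2$loci), 0L)
  expect_equal(nrow(grp2$singletons), 2L)

  # three genes with 200 bp gaps -> one triplet
  g3 <- make_genes(c(0, 1298, 2596), c(1098, 2396, 3694), "+")
  g3$bit_score <- 80
  grp3 <- group_adjacent(g3)
  expect_equal(grp3$loci$n_genes, 3L)

  # overlapping genes count as gap 0
  g4 <- make_genes(c(1000, 2000), c(2098, 3200), "+")
  g4$bit_score <- 80
  grp4 <- group_adjacent(g4)
  expect_equal(grp4$loci$max_internal_gap, 0L)

  # gap just above the limit splits the run
  g5 <- make_genes(c(1000, 7099), c(2098, 8200), "+")
  g5$bit_score <- 80
  expect_equal(nrow(group_adjacent(g5, max_gap = 5000L)$loci), 0L)
})

test_that("grouping is a partition and runs are maximal", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:12, 1L)
    starts <- cumsum(sample(1200:6000, n, replace = TRUE))
    g <- make_genes(starts, starts + 1098L,
                    sample(c("+", "-"), n, replace = TRUE),
                    contig = sample(c("c1", "c2"), 1L))
    g$bit_score <- 80
    grp <- group_adjacent(g, max_gap = 3000L)
    in_loci <- grp$genes$gene_id
    # partition: every candidate in exactly one of {locus genes, singletons}
    expect_equal(sort(c(in_loci, grp$singletons$gene_id)), sort(g$gene_id))
    expect_false(anyDuplicated(in_loci) > 0L)
    # maximality: no singleton is within max_gap of a same-strand locus end
    for (si in seq_len(nrow(grp$singletons))) {
      s <- grp$singletons[si, ]
      for (li in seq_len(nrow(grp$loci))) {
        loc <- grp$genes[grp$genes$locus_id == grp$loci$locus_id[li], ]
        if (s$contig_id != loc$contig_id[1L] ||
            s$strand != loc$strand[1L]) next
        gap_after <- s$start - max(loc$end)
        gap_before <- min(loc$start) - s$end
        expect_true(max(gap_after, gap_before) > 3000L ||
                      (gap_after < 0L && gap_before < 0L))
      }
    }
  }
})

test_that("pruning drops orphans, reduces triplets, and rejects contig-edge loci", {
  # 2-gene locus where one gene is not SpII and not rescued -> dropped
  g <- make_genes(c(1000, 2498), c(2098, 4000), "+")
  g$bit_score <- 80
  grp <- group_adjacent(g)
  grp$genes$signal_category <- c("SpII", "None")
  pruned <- prune_loci(grp)
  expect_equal(nrow(pruned$loci), 0L)
  # the SpII survivor is orphaned into singletons
  expect_true(g$gene_id[1L] %in% pruned$singletons$gene_id)

  # 3-gene locus with one SpI member -> reduced to a retained pair
  g3 <- make_genes(c(0, 1298, 2596), c(1098, 2396, 3694), "+")
  g3$bit_score <- 80
  grp3 <- group_adjacent(g3)
  grp3$genes$signal_category <- c("SpII", "SpI", "RescuedSpII")
  pruned3 <- prune_loci(grp3)
  expect_equal(pruned3$loci$n_genes, 2L)
  expect_equal(nrow(pruned3$genes), 2L)

  # gene ending exactly at the contig boundary kills the locus
  g4 <- make_genes(c(1000, 2498), c(2098, 4000), "+")
  g4$bit_score <- 80
  grp4 <- group_adjacent(g4)
  grp4$genes$signal_category <- "SpII"
  contigs <- data.frame(contig_id = "c1", length = 4000L)
  expect_equal(nrow(prune_loci(grp4, contigs)$loci), 0L)
  contigs_ok <- data.frame(contig_id = "c1", length = 8000L)
  expect_equal(nrow(prune_loci(grp4, contigs_ok)$loci), 1L)
})

test_that("the funnel is gene-wise monotone and recovers planted loci end to end", {
  gen <- generate_genomes(plant_spec(n_genomes = 12L, seed = 5L))
  res <- mine_loci(gen$genes, gen$hits, contigs = gen$contigs)
  f <- res$funnel
  expect_true(all(diff(unname(f[c("hits", "candidates", "in_runs",
                                  "retained")])) <= 0))
  truth <- gen$truth
  retained <- truth$gene_ids[truth$expected == "retained"]
  expect_setequal(res$loci$loci$gene_ids, retained)
  # decoys violating strand or gap surface as singletons
  single_genes <- unlist(strsplit(
    truth$gene_ids[truth$expected == "singleton"], ","))
  expect_true(all(single_genes %in% res$loci$singletons$gene_id))
})

test_that("an ingested signal-call table overrides the builtin heuristic", {
  gen <- generate_genomes(plant_spec(n_genomes = 2L, seed = 9L))
  truth <- gen$truth
  ret_genes <- unlist(strsplit(truth$gene_ids[truth$expected == "retained"],
                               ","))
  tab <- data.frame(protein_id = ret_genes[1L], category = "None",
                    stringsAsFactors = FALSE)
  res <- mine_loci(gen$genes, gen$hits, contigs = gen$contigs,
                   signal_table = tab)
  # overriding one member's call to None orphans its partner
  loci_genes <- unlist(strsplit(res$loci$loci$gene_ids, ","))
  expect_false(ret_genes[1L] %in% loci_genes)
})
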