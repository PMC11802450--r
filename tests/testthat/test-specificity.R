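test_that("transform_counts is ln(1 + x) and rejects negatives", {
  expect_equal(transform_counts(0), 0)
  expect_equal(transform_counts(exp(1) - 1), 1)
  expect_equal(transform_counts(10), 2.3979, tolerance = 1e-4)
  expect_error(transform_counts(-1), "nonnegative")
})

test_that("cluster_means averages transformed counts per cluster", {
  counts <- matrix(c(0, exp(1) - 1), nrow = 1,
                   dimnames = list("G1", c("c1", "c2")))
  expr <- cluster_means(counts, labels = c("A", "A"))
  expect_equal(expr$A, 0.5)
  expect_equal(unname(cells_per_cluster(expr)["A"]), 2L)

  # order invariance
  tc <- toy_counts()
  e1 <- cluster_means(tc$counts, tc$labels)
  perm <- c(3, 1, 4, 2)
  e2 <- cluster_means(tc$counts[, perm], tc$labels[perm])
  expect_equal(as.data.frame(e1), as.data.frame(e2))

  # empty factor level excluded with warning
  expect_warning(
    cluster_means(tc$counts, factor(tc$labels, levels = c("A", "B", "Z"))),
    "empty cluster")
})

test_that("filter_genes applies every removal rule and accounts for all genes", {
  counts <- matrix(1, nrow = 6, ncol = 4,
                   dimnames = list(paste0("G", 1:6), paste0("c", 1:4)))
  counts[4, ] <- 0  # unexpressed
  expr <- cluster_means(counts, labels = c("A", "A", "B", "B"))
  ann <- tibble::tibble(
    gene = paste0("G", 1:6),
    symbol = c("S1", "DUP1", "DUP1", "S4", "S5", "S6"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr6", "chr1"),
    start = c(1e5, 2e5, 3e5, 4e5, 24999000, 6e5),
    end = c(1.2e5, 2.2e5, 3.2e5, 4.2e5, 25001000, 6.2e5),
    strand = "+",
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "protein_coding", "protein_coding", "lncRNA"))
  out <- filter_genes(expr, ann)
  rep <- gene_filter_report(out)
  # G2,G3 nonunique name; G4 unexpressed; G5 overlaps MHC edge; G6 noncoding
  expect_identical(out$gene, "G1")
  expect_equal(sum(rep$n_removed), nrow(expr) - nrow(out))
  expect_equal(rep$n_removed[rep$rule == "nonunique_name"], 2)
  expect_equal(rep$n_removed[rep$rule == "unexpressed"], 1)
  expect_equal(rep$n_removed[rep$rule == "mhc"], 1)
  expect_equal(rep$n_removed[rep$rule == "non_protein_coding"], 1)

  # a gene with no annotation row counts as unmapped
  expr2 <- cluster_means(counts[1:2, ], labels = c("A", "A", "B", "B"))
  out2 <- filter_genes(expr2, ann[1, ])
  rep2 <- gene_filter_report(out2)
  expect_equal(rep2$n_removed[rep2$rule == "unmapped_id"], 1)

  # non-unique external id mapping removes the gene
  idmap <- tibble::tibble(gene = c("G1", "G2", "G3"),
                          entrez = c("1", "2", "2"))
  out3 <- filter_genes(expr2, ann, id_map = idmap)
  expect_false("G2" %in% out3$gene)
})

test_that("specificity rows sum to 1 and match the defining ratio", {
  counts <- matrix(c(2, 2, 1, 1, 1, 1), nrow = 1,
                   dimnames = list("G1", paste0("c", 1:6)))
  m <- cluster_means(exp(counts) - 1,
                     labels = rep(c("A", "B", "C"), each = 2))
  spec <- compute_specificity(m)
  expect_equal(unlist(spec[1, c("A", "B", "C")], use.names = FALSE),
               c(0.5, 0.25, 0.25))

  # evenly expressed gene scores 1/C everywhere
  even <- cluster_means(matrix(3, 1, 4, dimnames = list("G1", NULL)),
                        labels = paste0("K", 1:4))
  spec_even <- compute_specificity(even)
  expect_equal(unlist(spec_even[1, -1], use.names = FALSE), rep(0.25, 4))

  # row sums on simulated data
  cfg <- tiny_config(seed = 21L)
  sc <- simulate_expression(cfg)
  spec_big <- compute_specificity(
    filter_genes(cluster_means(sc), simulated_gene_annotation(cfg)))
  sums <- rowSums(as.matrix(spec_big[-1]))
  expect_lt(max(abs(sums - 1)), 1e-9)

  # scale covariance: scaling one gene's means leaves its row unchanged
  m2 <- cluster_means(toy_counts()$counts[1:2, ], toy_counts()$labels)
  scaled <- m2
  scaled$A <- scaled$A * 7
  scaled$B <- scaled$B * 7
  expect_equal(as.data.frame(compute_specificity(m2)),
               as.data.frame(compute_specificity(scaled)))

  # all-zero row is an error
  zero <- cluster_means(matrix(0, 1, 2, dimnames = list("G0", NULL)),
                        labels = c("A", "B"))
  expect_error(compute_specificity(zero), "all-zero")
})

test_that("downsampling caps cluster sizes, is seeded, and preserves ranking signal", {
  cfg <- simulation_config(n_haplotypes = 200L, n_chromosomes = 1L,
                           n_blocks_per_chrom = 10L, snps_per_block = 5L,
                           n_genes = 200L, n_clusters = 6L,
                           cells_per_cluster = 100L, seed = 31L)
  sc <- simulate_expression(cfg)

  ds <- downsample_clusters(sc, max_cells = 34L, seed = 4L)
  expect_true(all(table(ds$cells$cluster) == 34L))
  ds2 <- downsample_clusters(sc, max_cells = 34L, seed = 4L)
  expect_identical(ds$cells$cell, ds2$cells$cell)

  # max_cells above every cluster size is a no-op
  ds_all <- downsample_clusters(sc, max_cells = 1000L, seed = 4L)
  expect_identical(dim(ds_all$counts), dim(sc$counts))

  # specificity columns remain positively rank-correlated after
  # downsampling to 34 cells
  ann <- simulated_gene_annotation(cfg)
  full <- compute_specificity(filter_genes(cluster_means(sc), ann))
  small <- compute_specificity(filter_genes(cluster_means(ds), ann))
  shared <- intersect(full$gene, small$gene)
  rho <- cor(full$C1[match(shared, full$gene)],
             small$C1[match(shared, small$gene)], method = "spearman")
  expect_gt(rho, 0)
})
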