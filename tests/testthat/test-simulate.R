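test_that("config validation rejects degenerate settings", {
  expect_error(simulation_config(within_block_r = 1), "within_block_r")
  expect_error(simulation_config(enrichment_effect = 0.5), "enrichment_effect")
  expect_error(simulation_config(cells_per_cluster = 0), "cells_per_cluster")
  expect_error(simulation_config(causal_clusters = 99), "causal_clusters")
  expect_error(simulation_config(n_haplotypes = 0), "n_haplotypes")
})

test_that("reference panel has block LD structure and is deterministic", {
  cfg0 <- simulation_config(n_haplotypes = 2000L, n_chromosomes = 1L,
                            n_blocks_per_chrom = 30L, snps_per_block = 5L,
                            within_block_r = 0, n_genes = 50L, seed = 11L)
  panel0 <- simulate_reference_panel(cfg0)
  # independence: mean off-diagonal |r| small within blocks
  offdiag <- unlist(lapply(split(panel0$snps$snp, panel0$snps$block),
    function(s) {
      R <- cor(panel0$genotypes[, s])
      abs(R[upper.tri(R)])
    }))
  expect_lt(mean(offdiag), 0.1)

  cfg8 <- simulation_config(n_haplotypes = 2000L, n_chromosomes = 1L,
                            n_blocks_per_chrom = 10L, snps_per_block = 5L,
                            within_block_r = 0.8, n_genes = 50L, seed = 11L)
  panel8 <- simulate_reference_panel(cfg8)
  R <- cor(panel8$genotypes[, panel8$snps$snp[panel8$snps$block == 1]])
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(lam[1], 1)
  expect_equal(sum(lam), 5, tolerance = 1e-6)
  # realized genotype correlation lands near the requested block r
  expect_gt(mean(R[upper.tri(R)]), 0.55)

  # positions strictly increasing per chromosome
  expect_true(all(diff(panel8$snps$pos) > 0))

  # determinism
  panel8b <- simulate_reference_panel(cfg8)
  expect_identical(panel8$genotypes, panel8b$genotypes)
})

test_that("expression enrichment raises causal-gene specificity; none without it", {
  # no planted signal: causal-gene specificity centred on 1/n_clusters
  base <- list(n_haplotypes = 200L, n_chromosomes = 1L,
               n_blocks_per_chrom = 10L, snps_per_block = 5L,
               n_genes = 200L, n_clusters = 10L, cells_per_cluster = 30L,
               causal_clusters = 1L, causal_gene_fraction = 1)
  cfg_null <- do.call(simulation_config,
                      c(base, list(enrichment_effect = 1, seed = 5L)))
  truth_null <- make_ground_truth(cfg_null)
  sc <- simulate_expression(cfg_null, truth_null)
  spec <- compute_specificity(filter_genes(cluster_means(sc),
                                           simulated_gene_annotation(cfg_null)))
  s_causal <- spec$C1[spec$gene %in% truth_null$causal_genes[["1"]]]
  expect_gt(t.test(s_causal, mu = 1 / 10)$p.value, 0.01)

  cfg_enr <- do.call(simulation_config,
                     c(base, list(enrichment_effect = 10, seed = 5L)))
  truth_enr <- make_ground_truth(cfg_enr)
  sc_enr <- simulate_expression(cfg_enr, truth_enr)
  spec_enr <- compute_specificity(filter_genes(cluster_means(sc_enr),
                                               simulated_gene_annotation(cfg_enr)))
  s_enr <- spec_enr$C1[spec_enr$gene %in% truth_enr$causal_genes[["1"]]]
  expect_gt(mean(s_enr), 1 / 10)
})

test_that("null GWAS p-values are uniform; planted gene is detected", {
  cfg <- simulation_config(n_haplotypes = 1000L, n_chromosomes = 2L,
                           n_blocks_per_chrom = 100L, snps_per_block = 5L,
                           within_block_r = 0, n_genes = 100L,
                           gwas_effect_scale = 0, seed = 2L)
  ds_gwas <- simulate_gwas(cfg)
  expect_gt(ks.test(ds_gwas$p, "punif")$p.value, 0.01)

  # a planted gene at noncentrality 30 reaches P < 1e-4 in most replicates
  hits <- vapply(1:20, function(i) {
    cfg_i <- tiny_config(seed = 100L + i)
    truth <- make_ground_truth(cfg_i)
    panel <- simulate_reference_panel(cfg_i)
    gwas <- simulate_gwas(cfg_i, truth, panel)
    ga <- run_gene_analysis(gwas, simulated_gene_annotation(cfg_i), panel,
                            compute_correlation = FALSE)
    gene1 <- truth$causal_genes[[1]][1]
    ga$stats$p[ga$stats$gene == gene1] < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("generators are pure functions of config and seed", {
  cfg <- tiny_config(seed = 9L)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$gwas$p, ds2$gwas$p)
  expect_identical(as.matrix(ds1$expression$counts),
                   as.matrix(ds2$expression$counts))
  expect_identical(ds1$truth$causal_genes, ds2$truth$causal_genes)
})

test_that("power to detect the planted cluster rises with effect sizes", {
  # 3-point grid in each of the two effect knobs, small replicates
  mean_stat <- function(scale, enrich) {
    mean(vapply(1:6, function(i) {
      cfg <- tiny_config(seed = 300L + i, enrichment_effect = enrich)
      cfg$gwas_effect_scale <- scale
      res <- run_synthetic_pipeline(cfg, select = FALSE)
      -log10(res$scan$p[res$scan$cell_type == "C1"])
    }, numeric(1)))
  }
  by_scale <- c(mean_stat(0, 10), mean_stat(10 / 320404, 10),
                mean_stat(30 / 320404, 10))
  expect_true(all(diff(by_scale) > 0))
  by_enrich <- c(mean_stat(30 / 320404, 1), mean_stat(30 / 320404, 3),
                 mean_stat(30 / 320404, 10))
  expect_true(all(diff(by_enrich) > 0))
})
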