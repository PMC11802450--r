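test_that("SNP-to-gene windows are strand-aware and boundary-inclusive", {
  genes <- tibble::tibble(gene = c("plus", "minus"), chrom = "chr1",
                          start = 100000L, end = 110000L,
                          strand = c("+", "-"))
  snps <- tibble::tibble(
    snp = c("up_in", "up_out", "down_in", "down_out"),
    chrom = "chr1",
    pos = c(65000L, 64999L, 120000L, 120001L))
  models <- suppressWarnings(annotate_snps_to_genes(snps, genes))
  plus <- models$snps[[which(models$gene == "plus")]]
  minus <- models$snps[[which(models$gene == "minus")]]
  # '+' gene: [start - 35k, end + 10k] = [65000, 120000]
  expect_true(all(c("up_in", "down_in") %in% plus))
  expect_false("up_out" %in% plus)
  expect_false("down_out" %in% plus)
  # '-' gene: [start - 10k, end + 35k] = [90000, 145000]
  expect_false("up_in" %in% minus)
  expect_true(all(c("down_in", "down_out") %in% minus))

  # a SNP inside two overlapping genes maps to both
  genes2 <- tibble::tibble(gene = c("g1", "g2"), chrom = "chr1",
                           start = c(100000L, 105000L),
                           end = c(110000L, 115000L), strand = "+")
  snp2 <- tibble::tibble(snp = "shared", chrom = "chr1", pos = 107000L)
  m2 <- annotate_snps_to_genes(snp2, genes2)
  expect_equal(m2$n_snps, c(1L, 1L))

  # inconsistent chromosome naming errors
  expect_error(
    annotate_snps_to_genes(snps, dplyr::mutate(genes, chrom = "1")),
    "chromosome naming")
})

test_that("probit transform of SNP p-values", {
  expect_equal(snp_z_from_p(0.5), 0)
  expect_equal(snp_z_from_p(0.05), 1.6449, tolerance = 1e-4)
  expect_true(is.finite(snp_z_from_p(1)) && snp_z_from_p(1) < -5)
  expect_true(is.finite(snp_z_from_p(1e-310)))
  expect_error(snp_z_from_p(0), "0, 1")
  expect_error(snp_z_from_p(1.5), "0, 1")
})

test_that("gene statistic is the sum of squares and monotone in |z|", {
  expect_equal(gene_statistic(c(0, 0, 0)), 0)
  expect_equal(gene_statistic(c(1, 2)), 5)
  expect_error(gene_statistic(numeric(0)), "at least one")
  z <- c(0.5, -1.2, 2)
  for (i in seq_along(z)) {
    z2 <- z
    z2[i] <- z2[i] * 1.5
    expect_gt(gene_statistic(z2), gene_statistic(z))
  }
})

test_that("LD eigenvalues conserve the trace and match closed forms", {
  # independent SNPs: eigenvalues near 1
  g <- withr::with_seed(1, matrix(rbinom(5000 * 4, 2, 0.3), 5000, 4))
  lam <- ld_eigenvalues(g)
  expect_equal(sum(lam), 4, tolerance = 1e-6)
  expect_lt(max(abs(lam - 1)), 0.2)

  # perfectly correlated pair: (2, 0); the zero component is pruned
  g2 <- cbind(g[, 1], g[, 1])
  lam2 <- ld_eigenvalues(g2)
  expect_equal(as.numeric(lam2), 2)
  expect_equal(attr(lam2, "n_pruned") + length(lam2), 2L)
  expect_equal(attr(lam2, "trace"), 2, tolerance = 1e-9)

  # 5-SNP equicorrelation at r = 0.8: lambda = (4.2, 0.2 x4)
  R <- matrix(0.8, 5, 5); diag(R) <- 1
  lam3 <- ld_eigenvalues(R)
  expect_equal(as.numeric(lam3), c(4.2, rep(0.2, 4)), tolerance = 1e-9)

  # zero-variance SNP removed with warning
  expect_warning(ld_eigenvalues(cbind(g[, 1], rep(1, 5000))), "zero-variance")
})

test_that("mixture p-value matches closed forms and a Monte-Carlo oracle", {
  expect_equal(as.numeric(mixture_pvalue(0, c(1, 1))), 1)
  expect_equal(as.numeric(mixture_pvalue(3, c(1, 1))), exp(-1.5),
               tolerance = 1e-9)
  expect_equal(as.numeric(mixture_pvalue(qnorm(0.95)^2, 1)), 0.1,
               tolerance = 1e-9)
  expect_error(mixture_pvalue(-1, 1), "nonnegative")
  expect_error(mixture_pvalue(1, numeric(0)), "positive")

  # the Imhof route agrees with the exact chi-square when weights are equal
  for (Tq in c(1, 5, 12)) {
    expect_lt(abs(as.numeric(mixture_pvalue(Tq, c(1, 1, 1), method = "imhof")) -
                    pchisq(Tq, 3, lower.tail = FALSE)), 1e-9)
  }

  # unequal weights against brute-force Monte Carlo
  lam <- c(4.2, 0.2, 0.2, 0.2, 0.2)
  for (Tq in c(2, 6, 15)) {
    expect_lt(abs(as.numeric(mixture_pvalue(Tq, lam)) -
                    mc_quadform_tail(Tq, lam)), 0.01)
  }

  # monotone non-increasing in T; saddlepoint takes over in the far tail
  ps <- vapply(c(1, 10, 30, 60, 120), function(Tq) {
    as.numeric(mixture_pvalue(Tq, lam))
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_gt(ps[5], 0)
})

test_that("gene-gene correlation matches null covariance and its oracle", {
  cfg <- tiny_config(seed = 13L)
  panel <- simulate_reference_panel(cfg)

  # duplicated gene (same SNP set) has correlation 1
  snp_set <- panel$snps$snp[1:5]
  models <- structure(tibble::tibble(
    gene = c("a", "b"), chrom = "chr1",
    window_start = c(1L, 1L), window_end = c(2L, 2L),
    n_snps = 5L, snps = list(snp_set, snp_set)),
    class = c("gene_models", class(tibble::tibble())))
  corr <- gene_gene_correlation(models, panel)
  expect_equal(corr["a", "b"], 1, tolerance = 1e-6)

  # disjoint chromosomes are uncorrelated
  snp_far <- panel$snps$snp[panel$snps$chrom == "chr2"][1:5]
  models2 <- structure(tibble::tibble(
    gene = c("a", "b"), chrom = c("chr1", "chr2"),
    window_start = 1L, window_end = 2L, n_snps = 5L,
    snps = list(snp_set, snp_far)),
    class = c("gene_models", class(tibble::tibble())))
  corr2 <- gene_gene_correlation(models2, panel)
  expect_equal(corr2["a", "b"], 0)

  # overlapping genes: analytic value vs Monte-Carlo corr of null statistics
  half <- panel$snps$snp[3:7]
  models3 <- structure(tibble::tibble(
    gene = c("a", "b"), chrom = "chr1",
    window_start = c(1L, 2L), window_end = c(3L, 4L),
    n_snps = 5L, snps = list(snp_set, half)),
    class = c("gene_models", class(tibble::tibble())))
  corr3 <- gene_gene_correlation(models3, panel)
  R <- celltypescan:::panel_correlation(panel, union(snp_set, half))
  mc <- withr::with_seed(7, {
    L <- chol(R + diag(1e-8, nrow(R)))
    z <- matrix(rnorm(10000 * nrow(R)), 10000) %*% L
    ia <- match(snp_set, colnames(R)); ib <- match(half, colnames(R))
    cor(rowSums(z[, ia]^2), rowSums(z[, ib]^2))
  })
  expect_equal(corr3["a", "b"], mc, tolerance = 0.05)
})

test_that("run_gene_analysis composes the stages and is null-calibrated", {
  # single-SNP gene with p = 0.05: T = 2.7055, P = 0.10
  panel <- list(
    genotypes = withr::with_seed(2, matrix(rbinom(600, 2, 0.4), 300, 2,
      dimnames = list(NULL, c("s1", "s2")))),
    snps = tibble::tibble(snp = c("s1", "s2"), chrom = "chr1",
                          pos = c(105000L, 500000L), block = 1:2,
                          maf = 0.4, mac = 200L))
  gwas <- tibble::tibble(snp = c("s1", "s2"), chrom = "chr1",
                         pos = c(105000L, 500000L), p = c(0.05, 0.5),
                         n = 1000L)
  genes <- tibble::tibble(gene = c("g1", "g2"), chrom = "chr1",
                          start = c(100000L, 498000L),
                          end = c(110000L, 502000L), strand = "+")
  ga <- run_gene_analysis(gwas, genes, panel)
  g1 <- ga$stats[ga$stats$gene == "g1", ]
  expect_equal(g1$stat, qnorm(0.95)^2, tolerance = 1e-9)
  expect_equal(g1$p, 0.10, tolerance = 1e-6)
  # all SNPs at p = 0.5 give T = 0 and P = 1
  g2 <- ga$stats[ga$stats$gene == "g2", ]
  expect_equal(g2$stat, 0)
  expect_equal(g2$p, 1)

  # unmapped SNPs are rejected
  expect_error(
    run_gene_analysis(dplyr::mutate(gwas, snp = c("s1", "zz")), genes, panel),
    "absent from the reference panel")

  # null calibration: independent SNPs, uniform gene P
  cfg <- simulation_config(n_haplotypes = 1000L, n_chromosomes = 2L,
                           n_blocks_per_chrom = 150L, snps_per_block = 5L,
                           within_block_r = 0, n_genes = 300L,
                           gwas_effect_scale = 0, seed = 17L)
  ds <- simulate_dataset(cfg)
  ga_null <- run_gene_analysis(ds$gwas, ds$annotation, ds$panel,
                               compute_correlation = FALSE)
  expect_gt(ks.test(ga_null$stats$p, "punif")$p.value, 0.01)
})
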