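# Shared fixtures and independent oracles used across the suite.

config_with <- function(defaults, seed, dots) {
  args <- utils::modifyList(defaults, dots)
  args$seed <- seed
  do.call(simulation_config, args)
}

# Small, fast config for unit tests.
tiny_config <- function(seed = 1L, ...) {
  config_with(list(
    n_haplotypes = 400L, n_chromosomes = 2L, n_blocks_per_chrom = 40L,
    snps_per_block = 5L, n_genes = 100L, n_clusters = 8L,
    cells_per_cluster = 20L, causal_clusters = 1L,
    gwas_effect_scale = 30 / 320404), seed, list(...))
}

# Mid-size config for the recovery and calibration experiments: 20 clusters,
# 200 genes, 2,000 SNPs.
recovery_config <- function(seed = 1L, ...) {
  config_with(list(
    n_haplotypes = 600L, n_chromosomes = 2L, n_blocks_per_chrom = 200L,
    snps_per_block = 5L, n_genes = 200L, n_clusters = 20L,
    cells_per_cluster = 30L, causal_clusters = 1L,
    enrichment_effect = 10, gwas_effect_scale = 30 / 320404), seed, list(...))
}

# Brute-force generalized least squares by explicit inverse: the oracle the
# whitened-QR implementation is checked against.
brute_gls <- function(y, X, V) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  bread <- solve(XtVi %*% X)
  beta <- bread %*% XtVi %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- as.numeric(t(res) %*% Vi %*% res) / df
  se <- unname(sqrt(sigma2 * diag(bread)))
  t_stat <- as.numeric(beta) / se
  list(beta = as.numeric(beta), se = se, t = t_stat, df = df,
       p_one_sided = pt(t_stat, df, lower.tail = FALSE))
}

# Monte-Carlo tail probability of sum(lambda_j * chisq_1) > q.
mc_quadform_tail <- function(q, lambda, n = 2e5, seed = 42) {
  withr::with_seed(seed, {
    draws <- matrix(rnorm(n * length(lambda))^2, ncol = length(lambda))
    mean(draws %*% lambda > q)
  })
}

# Minimal dense expression fixture: genes x cells counts with labels.
toy_counts <- function() {
  counts <- matrix(c(
    5, 5, 0, 0,   # G1: A-specific
    2, 2, 2, 2,   # G2: even
    0, 0, 0, 0),  # G3: unexpressed
    nrow = 3, byrow = TRUE,
    dimnames = list(c("G1", "G2", "G3"),
                    c("a1", "a2", "b1", "b2")))
  list(counts = counts, labels = c("A", "A", "B", "B"))
}

toy_annotation <- function(genes = c("G1", "G2", "G3"),
                           chrom = "chr1", biotype = "protein_coding") {
  tibble::tibble(
    gene = genes, symbol = paste0("S_", genes), chrom = chrom,
    start = seq(1e5, by = 1e5, length.out = length(genes)),
    end = seq(1e5, by = 1e5, length.out = length(genes)) + 2e4,
    strand = "+", biotype = biotype)
}
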