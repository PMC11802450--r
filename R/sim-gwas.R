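#' Simulate GWAS summary statistics with planted gene-level signal
#'
#' Per-SNP z-statistics are drawn block-wise from a multivariate normal whose
#' covariance is the *realized* genotype correlation of the block in the
#' reference panel, so the downstream LD adjustment (which estimates LD from
#' the same panel) sees a self-consistent null.  SNPs inside the annotation
#' window of a causal gene receive mean `sqrt(ncp_g / m_g)` where `ncp_g` is
#' the gene's planted noncentrality and `m_g` its member-SNP count, making
#' the expected gene sum-of-squares statistic `m_g + ncp_g`.  All other SNPs
#' have mean zero, so null genes' gene-level p-values are uniform.  Reported
#' p-values are two-sided normal tails.
#'
#' @param config A [simulation_config()].
#' @param truth A [make_ground_truth()] object.
#' @param panel A [simulate_reference_panel()] result; must share coordinates
#'   with the gene annotation.
#' @param annotation Gene annotation tibble; defaults to the config's
#'   synthetic annotation.
#' @return A tibble of summary statistics: `snp`, `chrom`, `pos`, `p`, `n`.
#' @export
simulate_gwas <- function(config, truth = make_ground_truth(config),
                          panel = simulate_reference_panel(config),
                          annotation = simulated_gene_annotation(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"),
            inherits(panel, "reference_panel"))
  snps <- panel$snps
  if (!all(annotation$chrom %in% snps$chrom)) {
    abort("annotation uses chromosomes absent from the panel")
  }

  mu <- setNames(numeric(nrow(snps)), snps$snp)
  if (length(truth$noncentrality)) {
    models <- annotate_snps_to_genes(
      snps, annotation[annotation$gene %in% names(truth$noncentrality), ],
      quiet = TRUE)
    for (i in seq_len(nrow(models))) {
      members <- models$snps[[i]]
      if (length(members) == 0L) next
      ncp <- truth$noncentrality[[models$gene[i]]]
      # Plant the signal along the leading LD eigenvector of the member
      # SNPs (a causal signal spread through LD), so the gene-level
      # noncentrality `ncp` lands on the dominant mixture component; each
      # coordinate is then inflated to undo the two-sided-p folding.
      R <- panel_correlation(panel, members)
      eig <- eigen(R, symmetric = TRUE)
      v1 <- eig$vectors[, 1]
      if (sum(v1) < 0) v1 <- -v1
      delta <- ncp * eig$values[1] * v1^2
      mu[members] <- mu[members] +
        sign(v1) * vapply(delta, calibrate_folded_mean, numeric(1))
    }
  }

  with_seed(derive_seed(config$seed, "gwas"), {
    z <- numeric(nrow(snps))
    blocks <- split(seq_len(nrow(snps)),
                    paste(snps$chrom, snps$block, sep = ":"))
    for (idx in blocks) {
      R <- panel_correlation(panel, snps$snp[idx])
      L <- chol(R + diag(1e-8, nrow(R)))
      z[idx] <- mu[idx] + drop(crossprod(L, rnorm(length(idx))))
    }
    tibble(snp = snps$snp, chrom = snps$chrom, pos = snps$pos,
           p = pmin(pmax(2 * pnorm(-abs(z)), 1e-300), 1),
           n = config$gwas_n)
  })
}

# The analysis pipeline folds SNP z-scores through the two-sided p-value
# (z~ = probit(1 - 2*pnorm(-|z|))), which attenuates a planted mean.  To
# plant a per-SNP noncentrality `delta` on the folded scale, solve
# E[z~(X)^2] = 1 + delta for the latent mean of X ~ N(mu, 1).
calibrate_folded_mean <- local({
  table <- NULL
  # fold to |x|; the integrand has a mild log singularity at 0, so use a
  # fine fixed trapezoid grid rather than adaptive quadrature
  expected_sq <- function(mu) {
    x <- seq(1e-8, mu + 10, length.out = 20001L)
    zt <- qnorm(pmin(pmax(2 * pnorm(x) - 1, 1e-300), 1 - 1e-16))
    y <- zt^2 * (stats::dnorm(x - mu) + stats::dnorm(x + mu))
    sum((y[-1] + y[-length(y)]) / 2) * (x[2] - x[1])
  }
  function(delta) {
    if (delta <= 0) return(0)
    # attenuation is negligible below the quadrature resolution
    if (delta < 0.01) return(sqrt(delta))
    if (is.null(table)) {
      mu_grid <- seq(0, 12, by = 0.05)
      table <<- list(mu = mu_grid,
                     delta = vapply(mu_grid, expected_sq, numeric(1)) - 1)
    }
    if (delta >= max(table$delta)) return(sqrt(delta))
    stats::approx(table$delta, table$mu, xout = delta)$y
  }
})

# Pearson correlation of panel genotypes for a SNP set; zero-variance SNPs
# get unit self-correlation and zero cross-correlation.  Uses a scaled
# crossproduct (BLAS) rather than cor() for speed on wide SNP sets.
panel_correlation <- function(panel, snp_ids) {
  g <- panel$genotypes[, snp_ids, drop = FALSE]
  n <- nrow(g)
  mu <- colMeans(g)
  sdv <- sqrt(colSums(g^2) / n - mu^2)
  ok <- sdv > 0
  R <- diag(1, length(snp_ids))
  if (sum(ok) > 1L) {
    gs <- sweep(sweep(g[, ok, drop = FALSE], 2, mu[ok]), 2, sdv[ok], "/")
    Rok <- crossprod(gs) / n
    diag(Rok) <- 1
    R[ok, ok] <- as.matrix(Rok)
  }
  dimnames(R) <- list(snp_ids, snp_ids)
  R
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running the three generators under one config, giving
#' every input the pipeline needs plus the planted ground truth.
#'
#' @inheritParams simulate_gwas
#' @param shared_causal_genes Passed to [make_ground_truth()].
#' @return A `sim_dataset` list: `config`, `truth`, `annotation`, `panel`,
#'   `expression`, `gwas`.
#' @export
#' @examples
#' ds <- simulate_dataset(simulation_config(
#'   n_haplotypes = 100, n_chromosomes = 1, n_blocks_per_chrom = 10,
#'   n_genes = 20, n_clusters = 4, cells_per_cluster = 5, seed = 42))
#' names(ds)
simulate_dataset <- function(config, shared_causal_genes = FALSE) {
  truth <- make_ground_truth(config, shared_causal_genes = shared_causal_genes)
  annotation <- simulated_gene_annotation(config)
  panel <- simulate_reference_panel(config)
  structure(list(
    config = config,
    truth = truth,
    annotation = annotation,
    panel = panel,
    expression = simulate_expression(config, truth),
    gwas = simulate_gwas(config, truth, panel, annotation)
  ), class = "sim_dataset")
}
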