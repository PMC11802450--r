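#' Null correlation between gene sum-of-squares statistics
#'
#' Under the null the gene statistics are quadratic forms in jointly normal
#' SNP z-scores, so `cov(T_g, T_h) = 2 * sum_{i in g, j in h} r_ij^2` where
#' `r_ij` is the panel LD between SNP i of gene g and SNP j of gene h, and
#' `var(T_g) = 2 * ||R_g||_F^2`.  The resulting correlation
#' `sum r_ij^2 / sqrt(||R_g||_F^2 * ||R_h||_F^2)` is computed for gene pairs
#' whose windows lie within `max_dist` bp on the same chromosome and is zero
#' elsewhere.  The matrix is ridge-repaired to positive semi-definiteness
#' (add `(|min eigenvalue| + 1e-8) I`, then rescaled to unit diagonal) if
#' needed.
#'
#' @param models A [annotate_snps_to_genes()] result.
#' @param panel A [simulate_reference_panel()]-shaped panel (list with
#'   `genotypes` and `snps`).
#' @param max_dist Proximity cutoff in bp beyond which gene pairs are
#'   treated as uncorrelated (default 5 Mb).
#' @return A symmetric `gene_correlation` matrix (dsCMatrix) with gene ids
#'   as dimnames.
#' @export
gene_gene_correlation <- function(models, panel, max_dist = 5e6) {
  G <- nrow(models)
  genes <- models$gene
  frob <- numeric(G)
  trip <- vector("list", 256L); ntrip <- 0L

  for (ch in unique(models$chrom)) {
    gi <- which(models$chrom == ch)
    ord <- gi[order(models$window_start[gi])]
    all_snps <- unique(unlist(models$snps[ord], use.names = FALSE))
    R <- panel_correlation(panel, all_snps)
    idx_of <- lapply(models$snps[ord], function(s) match(s, all_snps))
    for (a in seq_along(ord)) {
      Ra <- R[idx_of[[a]], idx_of[[a]], drop = FALSE]
      frob[ord[a]] <- sum(Ra^2)
    }
    for (a in seq_along(ord)) {
      for (b in seq_along(ord)) {
        if (b <= a) next
        gap <- models$window_start[ord[b]] - models$window_end[ord[a]]
        if (gap > max_dist) break
        cross <- sum(R[idx_of[[a]], idx_of[[b]], drop = FALSE]^2)
        r <- cross / sqrt(frob[ord[a]] * frob[ord[b]])
        if (r > 1e-8) {
          ntrip <- ntrip + 1L
          trip[[ntrip]] <- c(ord[a], ord[b], min(r, 1))
        }
      }
    }
  }

  tm <- if (ntrip) do.call(rbind, trip[seq_len(ntrip)]) else
    matrix(numeric(0), 0, 3)
  M <- sparseMatrix(i = c(seq_len(G), tm[, 1]), j = c(seq_len(G), tm[, 2]),
                    x = c(rep(1, G), tm[, 3]), dims = c(G, G),
                    symmetric = TRUE, dimnames = list(genes, genes))
  repair_psd(M)
}

# Ridge-repair a symmetric correlation-like matrix to PSD, keeping unit
# diagonal.  Dense eigen is fine at the gene counts this package targets.
repair_psd <- function(M) {
  dense <- as.matrix(M)
  ev <- min(eigen(dense, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 0) {
    delta <- abs(ev) + 1e-8
    dense <- dense + diag(delta, nrow(dense))
    dense <- stats::cov2cor(dense)
    M <- methods::as(methods::as(Matrix::Matrix(dense, sparse = TRUE),
                                 "symmetricMatrix"), "CsparseMatrix")
  }
  structure(M, class = class(M), repaired = ev < 0)
}

#' Gene-level association analysis from GWAS summary statistics
#'
#' Runs the full gene-analysis stage: SNP-to-gene annotation with
#' strand-aware windows, probit transformation of SNP p-values, the
#' sum-of-squares gene statistic, LD eigenvalues from the reference panel,
#' the weighted chi-square mixture p-value, the gene z-score
#' `probit(1 - P_g)`, per-gene covariates, and (optionally) the gene-gene
#' correlation induced by shared and adjacent LD.
#'
#' Covariates per gene: `n_snps` (gene size), `gene_density` (retained
#' eigenvalue count over SNP count, an effective-test ratio), `inv_mac`
#' (inverse mean minor-allele count), `mean_n` (mean GWAS sample size over
#' member SNPs), and the natural logs of each.
#'
#' @param gwas Summary-statistics tibble with columns `snp`, `chrom`,
#'   `pos`, `p`, `n`.
#' @param genes Gene annotation tibble (`gene`, `chrom`, `start`, `end`,
#'   optional `strand`).
#' @param panel Reference panel (list with `genotypes`, `snps`); every GWAS
#'   SNP must be present in the panel.
#' @param window_up,window_down Annotation window in bp.
#' @param compute_correlation Also compute [gene_gene_correlation()].
#' @return A `gene_analysis` list: `stats` (one row per gene: `gene`,
#'   `n_snps`, `stat`, `p`, `z`, covariates), `models`, and `corr` (or
#'   `NULL`).
#' @export
run_gene_analysis <- function(gwas, genes, panel, window_up = 35000L,
                              window_down = 10000L,
                              compute_correlation = TRUE) {
  req <- c("snp", "chrom", "pos", "p", "n")
  if (!all(req %in% names(gwas))) {
    abort(paste("gwas table must have columns:", paste(req, collapse = ", ")))
  }
  missing_snps <- setdiff(gwas$snp, panel$snps$snp)
  if (length(missing_snps)) {
    abort(sprintf("%d GWAS SNP(s) absent from the reference panel (e.g. %s)",
                  length(missing_snps), missing_snps[1]))
  }
  models <- annotate_snps_to_genes(gwas, genes, window_up, window_down)

  mac <- setNames(panel$snps$mac, panel$snps$snp)
  p_of <- setNames(gwas$p, gwas$snp)
  n_of <- setNames(gwas$n, gwas$snp)

  G <- nrow(models)
  stat <- p <- dens <- inv_mac <- mean_n <- numeric(G)
  for (i in seq_len(G)) {
    ms <- models$snps[[i]]
    z <- snp_z_from_p(p_of[ms])
    stat[i] <- gene_statistic(z)
    lam <- ld_eigenvalues(panel$genotypes[, ms, drop = FALSE])
    p[i] <- as.numeric(mixture_pvalue(stat[i], lam))
    dens[i] <- length(lam) / length(ms)
    inv_mac[i] <- 1 / mean(mac[ms])
    mean_n[i] <- mean(n_of[ms])
  }
  stats <- tibble(
    gene = models$gene, n_snps = models$n_snps, stat = stat, p = p,
    z = qnorm(pmin(p, 1 - 1e-16), lower.tail = FALSE),
    gene_density = dens, inv_mac = inv_mac, mean_n = mean_n,
    log_n_snps = log(models$n_snps), log_gene_density = log(dens),
    log_inv_mac = log(inv_mac), log_mean_n = log(mean_n))
  corr <- if (compute_correlation) gene_gene_correlation(models, panel) else NULL
  structure(list(stats = stats, models = models, corr = corr),
            class = "gene_analysis")
}

#' @export
print.gene_analysis <- function(x, ...) {
  cat(sprintf("<gene_analysis> %d genes; min P = %.3g\n",
              nrow(x$stats), min(x$stats$p)))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy gene_analysis
#' @export
tidy.gene_analysis <- function(x, ...) x$stats
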