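#' Truncate gene z-scores
#'
#' Clamps values below `mean - 3 sd` or above `mean + 6 sd` to those bounds,
#' preventing outlying genes from dominating the regression.  The mean and
#' sd are computed once on the raw vector; the operation is idempotent.
#'
#' @param z Numeric vector (length >= 2).
#' @return Truncated vector.
#' @export
truncate_gene_z <- function(z) {
  if (length(z) < 2L) abort("need at least 2 gene z-scores")
  s <- sd(z)
  if (!is.finite(s) || s == 0) {
    warn("zero variance in gene z-scores; returned unchanged")
    return(z)
  }
  m <- mean(z)
  pmin(pmax(z, m - 3 * s), m + 6 * s)
}

#' Truncate a specificity column
#'
#' Symmetric clamp at `mean +/- 5 sd`, computed once on the raw column.
#'
#' @param s Numeric vector (length >= 2).
#' @return Truncated vector.
#' @export
truncate_specificity <- function(s) {
  if (length(s) < 2L) abort("need at least 2 specificity values")
  sdev <- sd(s)
  if (!is.finite(sdev) || sdev == 0) {
    warn("zero variance in specificity column; returned unchanged")
    return(s)
  }
  m <- mean(s)
  pmin(pmax(s, m - 5 * sdev), m + 5 * sdev)
}

#' Per-test Bonferroni threshold
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  alpha / n_tests
}

# Drop covariate columns with (near-)zero variance; they are collinear with
# the intercept (e.g. a constant GWAS sample size).
drop_constant_cols <- function(C) {
  if (is.null(C) || ncol(C) == 0L) return(C)
  keep <- apply(C, 2, function(x) sd(x) > 1e-12 * (abs(mean(x)) + 1))
  C[, keep, drop = FALSE]
}

#' Generalized least squares fit of gene z-scores on a gene property
#'
#' Fits `Z = b0 + property * b1 + C * b2 + e` where `e` has correlation
#' matrix `V` (the LD-induced gene-gene correlation).  The system is
#' whitened by the Cholesky factor of `V` and solved by least squares;
#' `t = b1 / SE(b1)` with `G - (k + 2)` degrees of freedom (intercept,
#' property, k covariates), and the one-sided p-value tests `b1 > 0`.
#'
#' @param z Gene z-scores (already truncated by the caller if desired).
#' @param property The gene property of interest (e.g. one specificity
#'   column), same length and gene order as `z`.
#' @param covariates Optional numeric matrix of covariates (no intercept);
#'   constant columns are dropped.
#' @param correlation Gene-gene correlation matrix `V` (dense or sparse,
#'   genes in the same order), its upper Cholesky factor (pass via
#'   `chol_V`), or `NULL` for independent errors.
#' @param chol_V Optional precomputed `chol(V)` (upper triangular), which
#'   takes precedence over `correlation`.
#' @return A `gls_fit` object: list with `coefficients` tibble (`term`,
#'   `estimate`, `std_error`, `statistic`, `p_one_sided`), `df`, `sigma2`,
#'   `n`.
#' @export
gls_fit <- function(z, property, covariates = NULL, correlation = NULL,
                    chol_V = NULL) {
  n <- length(z)
  if (length(property) != n) abort("`z` and `property` lengths differ")
  C <- if (is.null(covariates)) NULL else drop_constant_cols(as.matrix(covariates))
  X <- cbind(`(Intercept)` = 1, property = property, C)
  if (is.null(chol_V) && !is.null(correlation)) {
    chol_V <- chol(as.matrix(correlation))
  }
  if (!is.null(chol_V)) {
    zw <- backsolve(chol_V, z, transpose = TRUE)
    Xw <- backsolve(chol_V, X, transpose = TRUE)
    colnames(Xw) <- colnames(X)
  } else {
    zw <- z
    Xw <- X
  }
  qrx <- qr(Xw)
  if (qrx$rank < ncol(Xw)) {
    bad <- colnames(Xw)[qrx$pivot[(qrx$rank + 1):ncol(Xw)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrx, zw)
  res <- zw - Xw %*% beta
  df <- n - ncol(Xw)
  if (df < 1L) abort("not enough genes for the requested design")
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrx))
  # qr.R columns follow pivot order; map SEs back to original columns
  se_full <- numeric(ncol(Xw))
  se_full[qrx$pivot] <- sqrt(sigma2 * diag(XtXinv))
  tstat <- beta / se_full
  structure(list(
    coefficients = tibble(
      term = colnames(Xw),
      estimate = as.numeric(beta),
      std_error = se_full,
      statistic = as.numeric(tstat),
      p_one_sided = pt(as.numeric(tstat), df = df, lower.tail = FALSE)),
    df = df, sigma2 = sigma2, n = n), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("<gls_fit> n = %d, df = %d\n", x$n, x$df))
  print(x$coefficients)
  invisible(x)
}

#' Tidiers for celltypescan fits and scans
#'
#' `tidy()` returns per-term or per-cell-type rows; `glance()` returns a
#' one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy gls_fit
#' @export
tidy.gls_fit <- function(x, ...) x$coefficients

#' @rdname tidiers
#' @method glance gls_fit
#' @export
glance.gls_fit <- function(x, ...) {
  tibble(n = x$n, df = x$df, sigma2 = x$sigma2)
}

# Assemble the shared pieces of a scan: joined gene universe, truncated Z,
# covariate matrix, Cholesky factor of the gene correlation.
build_scan_context <- function(gene_stats, specificity, correlation = NULL,
                               covariate_cols = c("n_snps", "gene_density",
                                                  "inv_mac", "mean_n",
                                                  "log_n_snps",
                                                  "log_gene_density",
                                                  "log_inv_mac",
                                                  "log_mean_n")) {
  if (inherits(gene_stats, "gene_analysis")) {
    if (is.null(correlation)) correlation <- gene_stats$corr
    gene_stats <- gene_stats$stats
  }
  genes <- intersect(gene_stats$gene, specificity$gene)
  if (length(genes) == 0L) {
    abort("no genes shared between the GWAS-side and expression-side tables")
  }
  st <- gene_stats[match(genes, gene_stats$gene), ]
  sp <- specificity[match(genes, specificity$gene), ]
  Z <- truncate_gene_z(st$z)
  cc <- intersect(covariate_cols, names(st))
  C <- if (length(cc)) drop_constant_cols(as.matrix(st[cc])) else NULL
  U <- NULL
  if (!is.null(correlation)) {
    V <- as.matrix(correlation)[genes, genes, drop = FALSE]
    U <- chol(V)
  }
  list(genes = genes, Z = Z, C = C, U = U, spec = sp)
}

#' Scan every cell type for association with a phenotype
#'
#' For each cell type (analysed separately), regresses truncated gene
#' z-scores on the cell type's truncated specificity column plus covariates
#' under LD-correlated errors, testing `b1 > 0` one-sidedly, and flags
#' Bonferroni significance at `alpha / n_celltypes`.
#'
#' @param gene_stats A [run_gene_analysis()] result, or its `stats` tibble.
#' @param specificity A [compute_specificity()] tibble.
#' @param correlation Gene-gene correlation; defaults to the one inside a
#'   `gene_analysis` object, or independence when absent.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return A `celltype_scan` tibble: `cell_type`, `beta`, `se`, `t_stat`,
#'   `df`, `p`, `bonf_sig`, ordered by ascending `p` with ties broken by
#'   cell-type id; attributes `alpha`, `threshold`, `n_celltypes`,
#'   `n_genes`.
#' @export
run_celltype_scan <- function(gene_stats, specificity, correlation = NULL,
                              alpha = 0.05) {
  ctx <- build_scan_context(gene_stats, specificity, correlation)
  cts <- celltype_cols(ctx$spec)
  if (length(cts) == 0L) abort("specificity table has no cell-type columns")
  thr <- bonferroni_threshold(alpha, length(cts))

  rows <- purrr::map(cts, function(ct) {
    s <- truncate_specificity(ctx$spec[[ct]])
    fit <- gls_fit(ctx$Z, s, covariates = ctx$C, chol_V = ctx$U)
    co <- fit$coefficients[fit$coefficients$term == "property", ]
    tibble(cell_type = ct, beta = co$estimate, se = co$std_error,
           t_stat = co$statistic, df = fit$df, p = co$p_one_sided)
  })
  out <- bind_rows(rows) %>%
    mutate(bonf_sig = .data$p < thr) %>%
    arrange(.data$p, .data$cell_type)
  structure(out,
            class = c("celltype_scan", class(tibble())),
            alpha = alpha, threshold = thr,
            n_celltypes = length(cts), n_genes = length(ctx$genes))
}

#' @rdname tidiers
#' @method glance celltype_scan
#' @export
glance.celltype_scan <- function(x, ...) {
  tibble(n_celltypes = attr(x, "n_celltypes"),
         n_genes = attr(x, "n_genes"),
         alpha = attr(x, "alpha"),
         threshold = attr(x, "threshold"),
         n_significant = sum(x$bonf_sig))
}
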