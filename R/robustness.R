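#' Expected significant counts under a permutation design
#'
#' Analytic expectation for a gene-label permutation null: with `n_perm`
#' permutations of `n_celltypes` tests each, `n_perm * n_celltypes * alpha`
#' results are expected at level `alpha` by chance.
#'
#' @param n_perm Number of permutations.
#' @param n_celltypes Cell types tested per permutation.
#' @param alpha Significance level (per test).
#' @return Expected count of significant results.
#' @export
#' @examples
#' permutation_expected_count(1000, 461, 0.05)        # 23050
#' permutation_expected_count(1000, 461, 0.05 / 461)  # 50
permutation_expected_count <- function(n_perm, n_celltypes, alpha) {
  check_count(n_perm, "n_perm")
  check_count(n_celltypes, "n_celltypes")
  stopifnot(alpha > 0, alpha <= 1)
  n_perm * n_celltypes * alpha
}

#' Gene-label permutation null for the cell-type scan
#'
#' Randomly permutes the gene labels of the gene-analysis result table
#' (each gene's z-score and covariates travel together, so both marginals
#' are preserved while the gene-to-specificity link is broken), reruns the
#' full cell-type scan per permutation, and tallies significant results at
#' `alpha` and at the Bonferroni threshold `alpha / n_celltypes`.  One
#' shuffle is shared by all cell types within a permutation.
#'
#' @inheritParams run_celltype_scan
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return A `permutation_summary` list: `n_permutations`, `n_celltypes`,
#'   `n_tests_total`, `n_significant_at_alpha`,
#'   `n_significant_at_bonferroni`, `expected_at_alpha`,
#'   `expected_at_bonferroni`, `alpha`, `seed`, and `p_values` (matrix of
#'   one-sided Ps, permutations x cell types).
#' @export
permutation_null <- function(gene_stats, specificity, correlation = NULL,
                             n_perm = 100L, alpha = 0.05, seed = 1L) {
  check_count(n_perm, "n_perm")
  ctx <- build_scan_context(gene_stats, specificity, correlation)
  cts <- celltype_cols(ctx$spec)
  C <- length(cts)
  thr <- bonferroni_threshold(alpha, C)

  # Whitened, truncated specificity designs are fixed across permutations;
  # only the response changes.
  designs <- lapply(cts, function(ct) {
    X <- cbind(`(Intercept)` = 1,
               property = truncate_specificity(ctx$spec[[ct]]), ctx$C)
    Xw <- if (is.null(ctx$U)) X else backsolve(ctx$U, X, transpose = TRUE)
    qrx <- qr(Xw)
    list(qrx = qrx, ncol = ncol(X))
  })

  G <- length(ctx$Z)
  pmat <- with_seed(derive_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(i) {
      zp <- truncate_gene_z(ctx$Z[sample.int(G)])
      zw <- if (is.null(ctx$U)) zp else backsolve(ctx$U, zp, transpose = TRUE)
      vapply(designs, function(d) {
        beta <- qr.coef(d$qrx, zw)
        res <- zw - qr.fitted(d$qrx, zw)
        df <- G - d$ncol
        sigma2 <- sum(res^2) / df
        XtXinv <- chol2inv(qr.R(d$qrx))
        se <- numeric(d$ncol)
        se[d$qrx$pivot] <- sqrt(sigma2 * diag(XtXinv))
        pt(beta[2] / se[2], df = df, lower.tail = FALSE)
      }, numeric(1))
    }, numeric(C))
  })
  pmat <- t(pmat)  # permutations x cell types
  colnames(pmat) <- cts

  structure(list(
    n_permutations = as.integer(n_perm),
    n_celltypes = C,
    n_tests_total = as.integer(n_perm) * C,
    n_significant_at_alpha = sum(pmat < alpha),
    n_significant_at_bonferroni = sum(pmat < thr),
    expected_at_alpha = permutation_expected_count(n_perm, C, alpha),
    expected_at_bonferroni = permutation_expected_count(n_perm, C, thr),
    alpha = alpha,
    seed = as.integer(seed),
    p_values = pmat
  ), class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("<permutation_summary> %d permutations x %d cell types\n",
              x$n_permutations, x$n_celltypes))
  cat(sprintf("  at alpha = %.3g: %d observed vs %.1f expected\n",
              x$alpha, x$n_significant_at_alpha, x$expected_at_alpha))
  cat(sprintf("  at Bonferroni: %d observed vs %.1f expected\n",
              x$n_significant_at_bonferroni, x$expected_at_bonferroni))
  invisible(x)
}

#' @rdname tidiers
#' @method glance permutation_summary
#' @export
glance.permutation_summary <- function(x, ...) {
  tibble(n_permutations = x$n_permutations, n_celltypes = x$n_celltypes,
         n_tests_total = x$n_tests_total,
         n_significant_at_alpha = x$n_significant_at_alpha,
         expected_at_alpha = x$expected_at_alpha,
         n_significant_at_bonferroni = x$n_significant_at_bonferroni,
         expected_at_bonferroni = x$expected_at_bonferroni)
}

#' Effective sample size of a case-control GWAS
#'
#' `n_eff = 4 / (1/cases + 1/controls)`: the balanced-design-equivalent
#' sample size; equals the total n when cases and controls are balanced.
#'
#' @param cases,controls Positive counts.
#' @return Effective sample size.
#' @export
#' @examples
#' effective_n(100, 100)  # 200
#' effective_n(50, 200)   # 160
effective_n <- function(cases, controls) {
  if (any(cases <= 0) || any(controls <= 0)) {
    abort("`cases` and `controls` must be positive")
  }
  4 / (1 / cases + 1 / controls)
}

#' Correlation between scan significance and cluster cell counts
#'
#' Pearson correlation between `-log10(P)` of the cell-type scan and the
#' number of cells per cell type, with its two-sided p-value: a check that
#' statistical significance is not driven by how many cells represent each
#' cell type.
#'
#' @param scan A [run_celltype_scan()] result.
#' @param cell_counts Named vector (or tibble with `cell_type`, `n_cells`)
#'   of cells per cell type.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @export
significance_vs_cellcount <- function(scan, cell_counts) {
  if (is.data.frame(cell_counts)) {
    cell_counts <- setNames(cell_counts$n_cells, cell_counts$cell_type)
  }
  common <- intersect(scan$cell_type, names(cell_counts))
  if (length(common) < 3L) abort("need at least 3 matching cell types")
  x <- -log10(scan$p[match(common, scan$cell_type)])
  y <- as.numeric(cell_counts[common])
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: constant -log10(P) or cell counts")
  }
  ct <- cor.test(x, y)
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}

#' Export specifically-expressed-gene genome annotations
#'
#' For each cell type, selects the `ceiling(top_fraction * G)` genes with
#' highest specificity (ties broken by gene id ascending), extends each
#' gene's interval by `window` bp on both sides (clipped at position 1),
#' and merges overlapping intervals.  Coordinates are 1-based inclusive;
#' use [write_seg_bed()] for 0-based half-open BED output.
#'
#' @param specificity A [compute_specificity()] tibble.
#' @param annotation Gene annotation with `gene`, `chrom`, `start`, `end`.
#' @param top_fraction Fraction of genes per cell type (default 0.10).
#' @param window Flank size in bp (default 100 kb).
#' @return Tibble: `cell_type`, `chrom`, `start`, `end`.
#' @export
export_seg_annotations <- function(specificity, annotation,
                                   top_fraction = 0.10, window = 100000L) {
  check_fraction(top_fraction, "top_fraction", 0, 1, inclusive_hi = TRUE)
  missing <- setdiff(specificity$gene, annotation$gene)
  if (length(missing)) {
    abort(sprintf("no coordinates for %d gene(s) (e.g. %s)",
                  length(missing), missing[1]))
  }
  G <- nrow(specificity)
  n_top <- ceiling(top_fraction * G)
  ann <- annotation[match(specificity$gene, annotation$gene), ]

  purrr::map_dfr(celltype_cols(specificity), function(ct) {
    ord <- order(-specificity[[ct]], specificity$gene)[seq_len(n_top)]
    purrr::map_dfr(unique(ann$chrom[ord]), function(ch) {
      sel <- ord[ann$chrom[ord] == ch]
      ir <- IRanges::reduce(IRanges::IRanges(
        start = pmax(ann$start[sel] - window, 1),
        end = ann$end[sel] + window))
      tibble(cell_type = ct, chrom = ch,
             start = IRanges::start(ir), end = IRanges::end(ir))
    })
  })
}

#' Power of the pipeline across GWAS sample sizes
#'
#' Reruns the full synthetic pipeline (fixed planted truth structure) at
#' each GWAS sample size and counts Bonferroni-significant cell types and
#' selected independent cell types, optionally over several replicates.
#' With a fixed per-participant effect scale, planted noncentrality (and so
#' detection power) grows with `gwas_n`.
#'
#' @param config Base [simulation_config()].
#' @param gwas_n_grid Increasing vector (length >= 2) of GWAS sample sizes.
#' @param n_replicates Replicates per grid point (seeds derived from the
#'   config seed).
#' @return A `power_curve` tibble: `gwas_n`, `replicate`,
#'   `n_significant_celltypes`, `n_selected_independent`, `top_hit_causal`.
#' @export
power_curve_harness <- function(config, gwas_n_grid, n_replicates = 1L) {
  if (length(gwas_n_grid) < 2L) abort("need at least 2 sample sizes")
  check_count(n_replicates, "n_replicates")
  rows <- purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
    purrr::map_dfr(seq_along(gwas_n_grid), function(k) {
      cfg <- config
      cfg$gwas_n <- as.integer(gwas_n_grid[k])
      cfg$seed <- config$seed + 1000L * rep_i
      res <- run_synthetic_pipeline(cfg)
      tibble(gwas_n = cfg$gwas_n, replicate = rep_i,
             n_significant_celltypes = sum(res$scan$bonf_sig),
             n_selected_independent = length(res$selection$selected),
             top_hit_causal = res$scan$cell_type[1] %in%
               paste0("C", cfg$causal_clusters))
    })
  })
  structure(rows, class = c("power_curve", class(tibble())))
}
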