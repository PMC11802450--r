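#' Simulate a cluster-labeled single-cell count matrix
#'
#' Cluster mean-expression profiles live on a binary hierarchy: a child
#' node's log-mean profile equals its parent's plus independent Gaussian
#' noise scaled by `1 - cluster_tree_correlation`, so sibling clusters share
#' correlated profiles (the structure the conditional analysis must
#' disentangle).  Causal genes have their mean multiplied by
#' `enrichment_effect` inside causal clusters.  Counts are negative binomial
#' (dispersion 0.5, i.e. size 2) with per-cell lognormal library factors
#' (sigma 0.3), reproducing the overdispersion and zeros that the
#' `ln(1 + x)` transform is meant to tame.
#'
#' @param config A [simulation_config()]; `n_clusters` must be at least 2.
#' @param truth A [make_ground_truth()] object.
#' @return An `sc_counts` list: `counts` (sparse genes x cells dgCMatrix),
#'   `cells` (tibble with `cell`, `cluster`), and `cluster_log_means`
#'   (genes x clusters matrix of the generative log-means).
#' @export
simulate_expression <- function(config, truth = make_ground_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (config$n_clusters < 2L) abort("`n_clusters` must be >= 2")
  if (config$enrichment_effect < 1) abort("`enrichment_effect` must be >= 1")
  if (config$cells_per_cluster < 1L) abort("`cells_per_cluster` must be >= 1")

  genes <- simulated_gene_annotation(config)$gene
  genes <- sort(genes)
  G <- length(genes)
  C <- config$n_clusters
  level_sd <- 0.8 * (1 - config$cluster_tree_correlation)

  with_seed(derive_seed(config$seed, "expression"), {
    base <- rnorm(G, mean = log(0.5), sd = 1)
    # walk a binary tree until at least C leaves exist
    profiles <- matrix(base, nrow = G, ncol = 1)
    while (ncol(profiles) < C) {
      profiles <- do.call(cbind, lapply(seq_len(ncol(profiles)), function(j) {
        cbind(profiles[, j] + rnorm(G, sd = level_sd),
              profiles[, j] + rnorm(G, sd = level_sd))
      }))
    }
    log_means <- profiles[, seq_len(C), drop = FALSE]
    rownames(log_means) <- genes
    colnames(log_means) <- paste0("C", seq_len(C))

    for (cl in names(truth$causal_genes)) {
      g <- truth$causal_genes[[cl]]
      log_means[g, as.integer(cl)] <-
        log_means[g, as.integer(cl)] + log(config$enrichment_effect)
    }

    n_cells <- C * config$cells_per_cluster
    cluster_of <- rep(seq_len(C), each = config$cells_per_cluster)
    lib <- exp(rnorm(n_cells, 0, 0.3))
    counts <- matrix(0L, G, n_cells)
    for (j in seq_len(n_cells)) {
      mu <- lib[j] * exp(log_means[, cluster_of[j]])
      counts[, j] <- rnbinom(G, size = 2, mu = mu)
    }
    dimnames(counts) <- list(genes, sprintf("cell%05d", seq_len(n_cells)))
    structure(list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      cells = tibble(cell = colnames(counts),
                     cluster = paste0("C", cluster_of)),
      cluster_log_means = log_means
    ), class = "sc_counts")
  })
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("<sc_counts> %d genes x %d cells in %d clusters (%.1f%% zeros)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$cluster)),
              100 * (1 - Matrix::nnzero(x$counts) / prod(dim(x$counts)))))
  invisible(x)
}
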