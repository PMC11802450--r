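#' Simulation configuration for the synthetic study
#'
#' Bundles every knob of the synthetic-data generator: a block-LD genotype
#' reference panel, a cluster-labeled single-cell count matrix with a planted
#' specificity enrichment, and GWAS summary statistics whose gene-level signal
#' is concentrated in genes specific to designated causal clusters.
#'
#' The defaults describe the study conditions used throughout the package's
#' own experiments: 500 genes on 5 synthetic chromosomes, 5,000 SNPs in
#' 5-SNP LD blocks, 20 cell-type clusters on a binary hierarchy, one causal
#' cluster, a 10-fold expression enrichment of causal genes, and per-gene
#' GWAS noncentrality `gwas_effect_scale * gwas_n`.
#'
#' @param n_haplotypes Haplotypes in the reference panel (two per diploid
#'   individual; must be even).
#' @param n_chromosomes Number of synthetic autosomes.
#' @param n_blocks_per_chrom LD blocks per chromosome.
#' @param snps_per_block SNPs per LD block.
#' @param within_block_r Latent pairwise correlation of SNPs within a block,
#'   in `[0, 1)`.
#' @param n_genes Total genes, placed end-to-end with 50-kb gaps.
#' @param n_clusters Cell-type clusters (at least 2).
#' @param causal_clusters Integer ids (1-based) of clusters carrying planted
#'   signal.
#' @param enrichment_effect Multiplier (>= 1) applied to causal-gene mean
#'   expression inside causal clusters.
#' @param gwas_effect_scale Per-gene noncentrality per GWAS participant; the
#'   planted gene-level noncentrality is `gwas_effect_scale * gwas_n`.
#' @param gwas_n GWAS sample size written to the summary statistics.
#' @param cells_per_cluster Cells simulated per cluster.
#' @param cluster_tree_correlation Correlation of sibling-cluster mean
#'   profiles on the binary cluster hierarchy, in `[0, 1)`.
#' @param causal_gene_fraction Fraction of genes assigned as causal to each
#'   causal cluster.
#' @param seed Root seed; all generator stages derive their streams from it.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 50, n_chromosomes = 1,
#'                          n_blocks_per_chrom = 20, seed = 1)
#' cfg$n_genes
simulation_config <- function(n_haplotypes = 2000L,
                              n_chromosomes = 5L,
                              n_blocks_per_chrom = 200L,
                              snps_per_block = 5L,
                              within_block_r = 0.8,
                              n_genes = 500L,
                              n_clusters = 20L,
                              causal_clusters = 1L,
                              enrichment_effect = 10,
                              gwas_effect_scale = 1e-4,
                              gwas_n = 320404L,
                              cells_per_cluster = 50L,
                              cluster_tree_correlation = 0.5,
                              causal_gene_fraction = 0.1,
                              seed = 1L) {
  check_count(n_haplotypes, "n_haplotypes", 2L)
  if (n_haplotypes %% 2L != 0L) abort("`n_haplotypes` must be even (two per individual)")
  check_count(n_chromosomes, "n_chromosomes")
  check_count(n_blocks_per_chrom, "n_blocks_per_chrom")
  check_count(snps_per_block, "snps_per_block")
  check_fraction(within_block_r, "within_block_r", 0, 1)
  check_count(n_genes, "n_genes")
  check_count(n_clusters, "n_clusters")
  causal_clusters <- as.integer(causal_clusters)
  if (length(causal_clusters) &&
      (any(causal_clusters < 1L) || any(causal_clusters > n_clusters))) {
    abort("`causal_clusters` must be cluster ids in 1..n_clusters")
  }
  if (anyDuplicated(causal_clusters)) abort("`causal_clusters` must be distinct")
  if (enrichment_effect < 1) abort("`enrichment_effect` must be >= 1")
  if (gwas_effect_scale < 0) abort("`gwas_effect_scale` must be >= 0")
  check_count(gwas_n, "gwas_n")
  check_count(cells_per_cluster, "cells_per_cluster")
  check_fraction(cluster_tree_correlation, "cluster_tree_correlation", 0, 1)
  check_fraction(causal_gene_fraction, "causal_gene_fraction", 0, 1, inclusive_hi = TRUE)
  check_count(seed, "seed", 0L)

  structure(list(
    n_haplotypes = as.integer(n_haplotypes),
    n_chromosomes = as.integer(n_chromosomes),
    n_blocks_per_chrom = as.integer(n_blocks_per_chrom),
    snps_per_block = as.integer(snps_per_block),
    within_block_r = within_block_r,
    n_genes = as.integer(n_genes),
    n_clusters = as.integer(n_clusters),
    causal_clusters = causal_clusters,
    enrichment_effect = enrichment_effect,
    gwas_effect_scale = gwas_effect_scale,
    gwas_n = as.integer(gwas_n),
    cells_per_cluster = as.integer(cells_per_cluster),
    cluster_tree_correlation = cluster_tree_correlation,
    causal_gene_fraction = causal_gene_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  panel: %d haplotypes, %d chrom x %d blocks x %d SNPs (r = %.2f)\n",
              x$n_haplotypes, x$n_chromosomes, x$n_blocks_per_chrom,
              x$snps_per_block, x$within_block_r))
  cat(sprintf("  expression: %d genes, %d clusters x %d cells (tree rho = %.2f)\n",
              x$n_genes, x$n_clusters, x$cells_per_cluster,
              x$cluster_tree_correlation))
  cat(sprintf("  signal: clusters {%s}, enrichment %.1f, ncp %.1f (n = %d)\n",
              paste(x$causal_clusters, collapse = ","), x$enrichment_effect,
              x$gwas_effect_scale * x$gwas_n, x$gwas_n))
  invisible(x)
}

# Gene annotation implied by the config: genes laid end-to-end per
# chromosome, 20-kb bodies separated by 50-kb gaps, all on '+'.
GENE_LENGTH <- 20000L
GENE_GAP <- 50000L

#' Synthetic gene annotation for a simulation configuration
#'
#' Genes are distributed round-robin across chromosomes and placed
#' end-to-end with 50-kb intergenic gaps; coordinates are 1-based inclusive.
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `gene`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`.
#' @export
simulated_gene_annotation <- function(config) {
  n <- config$n_genes
  chrom_of <- ((seq_len(n) - 1L) %% config$n_chromosomes) + 1L
  idx_on_chrom <- (seq_len(n) - 1L) %/% config$n_chromosomes
  start <- 1L + idx_on_chrom * (GENE_LENGTH + GENE_GAP)
  tibble(
    gene = sprintf("G%04d", seq_len(n)),
    symbol = sprintf("SYM%04d", seq_len(n)),
    chrom = paste0("chr", chrom_of),
    start = start,
    end = start + GENE_LENGTH - 1L,
    strand = "+",
    biotype = "protein_coding"
  ) %>%
    arrange(.data$chrom, .data$start)
}

#' Plant the ground truth for a synthetic study
#'
#' Assigns a disjoint causal gene set to each causal cluster (a fraction
#' `causal_gene_fraction` of all genes per cluster, sampled without
#' replacement under the config seed) and a per-gene GWAS noncentrality of
#' `gwas_effect_scale * gwas_n`.  Passing `shared_causal_genes = TRUE` gives
#' every causal cluster the *same* gene set, the construction used to study
#' signal shared between correlated sibling clusters.
#'
#' @param config A [simulation_config()].
#' @param shared_causal_genes If `TRUE`, all causal clusters share one gene
#'   set.
#' @return A `ground_truth` list: `causal_clusters`, `causal_genes` (named
#'   list of gene-id vectors), `noncentrality` (named per-gene vector).
#' @export
make_ground_truth <- function(config, shared_causal_genes = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  ann <- simulated_gene_annotation(config)
  ncausal <- max(1L, round(config$causal_gene_fraction * config$n_genes))
  ncp <- config$gwas_effect_scale * config$gwas_n
  causal <- with_seed(derive_seed(config$seed, "truth"), {
    if (length(config$causal_clusters) == 0L) {
      list()
    } else if (shared_causal_genes) {
      shared <- sample(ann$gene, ncausal)
      setNames(rep(list(shared), length(config$causal_clusters)),
               as.character(config$causal_clusters))
    } else {
      pool <- sample(ann$gene)   # disjoint draws from a shuffled pool
      need <- ncausal * length(config$causal_clusters)
      if (need > length(pool)) {
        abort("causal_gene_fraction too large for disjoint causal gene sets")
      }
      sets <- split(pool[seq_len(need)],
                    rep(seq_along(config$causal_clusters), each = ncausal))
      setNames(lapply(sets, sort), as.character(config$causal_clusters))
    }
  })
  genes <- unique(unlist(causal, use.names = FALSE))
  structure(list(
    causal_clusters = config$causal_clusters,
    causal_genes = causal,
    noncentrality = setNames(rep(ncp, length(genes)), genes)
  ), class = "ground_truth")
}
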