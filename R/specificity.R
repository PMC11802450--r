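#' Log-transform expression counts
#'
#' The `ln(1 + x)` transform typically applied to single-cell counts to
#' compress the scale and reduce outliers.
#'
#' @param x Nonnegative counts (vector or matrix).
#' @return `log(1 + x)`, elementwise.
#' @export
#' @examples
#' transform_counts(c(0, exp(1) - 1, 10))
transform_counts <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("counts must be nonnegative")
  log1p(x)
}

new_cluster_expr <- function(df, cells_per_cluster) {
  structure(df,
            cells_per_cluster = cells_per_cluster,
            class = c("cluster_expr", class(tibble())))
}

#' Cells per cluster recorded on a cluster-expression table
#' @param expr A [cluster_means()] result.
#' @return Named integer vector of cluster sizes.
#' @export
cells_per_cluster <- function(expr) attr(expr, "cells_per_cluster")

#' Mean transformed expression per gene and cluster
#'
#' Applies [transform_counts()] to every count and averages over the cells
#' of each cluster, yielding the mean-transformed expression of each gene in
#' each cell type.
#'
#' @param counts Genes x cells count matrix (dense or `dgCMatrix`), or an
#'   `sc_counts` object from [simulate_expression()].
#' @param labels Cluster label per cell: a character/factor vector along the
#'   columns of `counts`, or a tibble with columns `cell` and `cluster`.
#'   Ignored when `counts` is an `sc_counts` object.
#' @return A `cluster_expr` tibble: a `gene` column plus one numeric column
#'   per cluster, with cluster cell counts in `attr(, "cells_per_cluster")`
#'   (see [cells_per_cluster()]).  Empty clusters are excluded with a
#'   warning.
#' @export
cluster_means <- function(counts, labels = NULL) {
  if (inherits(counts, "sc_counts")) {
    labels <- counts$cells
    counts <- counts$counts
  }
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels$cluster), labels$cell)[colnames(counts)]
  }
  if (length(labels) != ncol(counts) || anyNA(labels)) {
    abort("every cell must have exactly one cluster label")
  }
  clusters <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  empty <- setdiff(clusters, labels)
  if (length(empty)) {
    warn(paste("excluding empty cluster(s):", paste(empty, collapse = ", ")))
    clusters <- setdiff(clusters, empty)
  }
  lx <- transform_counts(counts)
  m <- vapply(clusters, function(cl) {
    idx <- which(labels == cl)
    Matrix::rowMeans(lx[, idx, drop = FALSE])
  }, numeric(nrow(counts)))
  sizes <- vapply(clusters, function(cl) sum(labels == cl), integer(1))
  genes <- rownames(counts)
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(nrow(counts)))
  if (nrow(counts) == 1L) m <- matrix(m, nrow = 1, dimnames = list(genes, clusters))
  df <- as_tibble(as.data.frame(m))
  df <- dplyr::bind_cols(tibble(gene = genes), df)
  new_cluster_expr(df, sizes)
}

#' Filter genes before specificity scoring
#'
#' Applies, in order: keep protein-coding genes only; drop genes without
#' annotation or without a unique id mapping; drop genes with non-unique
#' symbols; drop genes overlapping the MHC interval (any overlap, 1-based
#' inclusive coordinates); drop unexpressed genes (zero total mean
#' expression).  Each removed gene is counted once, under the first rule
#' that fires.
#'
#' @param expr A [cluster_means()] result.
#' @param annotation Tibble with columns `gene`, `symbol`, `chrom`, `start`,
#'   `end`, `biotype`.
#' @param id_map Optional tibble mapping `gene` to an external id column
#'   (e.g. Entrez); genes whose mapping is missing or non-unique on either
#'   side are removed.
#' @param mhc Length-2 numeric, the MHC interval bounds (1-based inclusive).
#' @param mhc_chrom Chromosome name carrying the MHC interval.
#' @return The filtered `cluster_expr`, with a tibble of per-rule removal
#'   counts in `attr(, "filter_report")` (see [gene_filter_report()]).
#' @export
filter_genes <- function(expr, annotation, id_map = NULL,
                         mhc = c(25000000, 34000000), mhc_chrom = "chr6") {
  stopifnot(inherits(expr, "cluster_expr"))
  req <- c("gene", "symbol", "chrom", "start", "end", "biotype")
  if (!all(req %in% names(annotation))) {
    abort(paste("annotation must have columns:", paste(req, collapse = ", ")))
  }
  genes <- expr$gene
  reason <- setNames(rep(NA_character_, length(genes)), genes)

  ann <- annotation[match(genes, annotation$gene), ]
  unmapped <- is.na(ann$gene)
  noncoding <- !unmapped & ann$biotype != "protein_coding"
  reason[noncoding & is.na(reason)] <- "non_protein_coding"
  reason[unmapped & is.na(reason)] <- "unmapped_id"

  if (!is.null(id_map)) {
    if (!"gene" %in% names(id_map) || ncol(id_map) < 2L) {
      abort("`id_map` must have a `gene` column and one id column")
    }
    ext <- id_map[[setdiff(names(id_map), "gene")[1]]]
    bad_map <- id_map$gene[duplicated(id_map$gene) | duplicated(id_map$gene, fromLast = TRUE) |
                             duplicated(ext) | duplicated(ext, fromLast = TRUE) |
                             is.na(ext)]
    no_map <- !genes %in% id_map$gene | genes %in% bad_map
    reason[no_map & is.na(reason)] <- "unmapped_id"
  }

  dup_sym <- ann$symbol %in% ann$symbol[duplicated(ann$symbol)]
  reason[!unmapped & dup_sym & is.na(reason)] <- "nonunique_name"

  in_mhc <- !unmapped & ann$chrom == mhc_chrom &
    ann$start <= mhc[2] & ann$end >= mhc[1]
  reason[in_mhc & is.na(reason)] <- "mhc"

  total <- rowSums(as_matrix_by_gene(expr))
  reason[total <= 0 & is.na(reason)] <- "unexpressed"

  keep <- is.na(reason)
  report <- tibble(
    rule = c("non_protein_coding", "unexpressed", "nonunique_name", "mhc",
             "unmapped_id"),
    n_removed = c(sum(reason == "non_protein_coding", na.rm = TRUE),
                  sum(reason == "unexpressed", na.rm = TRUE),
                  sum(reason == "nonunique_name", na.rm = TRUE),
                  sum(reason == "mhc", na.rm = TRUE),
                  sum(reason == "unmapped_id", na.rm = TRUE)))
  out <- new_cluster_expr(expr[keep, , drop = FALSE], cells_per_cluster(expr))
  attr(out, "filter_report") <- report
  out
}

#' Per-rule gene removal counts from [filter_genes()]
#' @param expr A filtered `cluster_expr`.
#' @return Tibble with columns `rule`, `n_removed`.
#' @export
gene_filter_report <- function(expr) attr(expr, "filter_report")

#' Expression specificity of each gene in each cell type
#'
#' Divides the mean-transformed expression of a gene in a cell type by the
#' sum of that gene's mean-transformed expression across all cell types,
#' giving a value in `[0, 1]` per gene and cell type; each gene's row sums
#' to 1.  A gene evenly expressed across C cell types scores `1/C`
#' everywhere.
#'
#' @param expr A filtered [cluster_means()] result with no all-zero genes.
#' @return A `specificity` tibble (gene column plus one column per cell
#'   type).
#' @export
#' @examples
#' expr <- cluster_means(matrix(c(2, 1, 1, 1, 1, 1), nrow = 1,
#'                              dimnames = list("G1", NULL)),
#'                       labels = rep(c("A", "B", "C"), each = 2))
#' compute_specificity(expr)
compute_specificity <- function(expr) {
  stopifnot(inherits(expr, "cluster_expr"))
  m <- as_matrix_by_gene(expr)
  total <- rowSums(m)
  if (any(total <= 0)) {
    abort("all-zero gene row(s) present; run filter_genes() first")
  }
  s <- m / total
  df <- dplyr::bind_cols(tibble(gene = expr$gene),
                         as_tibble(as.data.frame(s)))
  structure(df, class = c("specificity", class(tibble())))
}

#' Downsample cells within each cluster
#'
#' Retains at most `max_cells` cells per cluster, sampled uniformly without
#' replacement, used to probe how specificity scores (and downstream
#' cell-type associations) degrade when cell types are represented by few
#' cells.
#'
#' @param counts Genes x cells count matrix, or an `sc_counts` object.
#' @param labels As in [cluster_means()].
#' @param max_cells Maximum cells retained per cluster (>= 1).
#' @param seed Integer seed for the sampling.
#' @return A list with the subset `counts` and `labels` (tibble with `cell`,
#'   `cluster`); for `sc_counts` input, an `sc_counts` object.
#' @export
downsample_clusters <- function(counts, labels = NULL, max_cells, seed = 1L) {
  check_count(max_cells, "max_cells")
  is_sc <- inherits(counts, "sc_counts")
  if (is_sc) {
    obj <- counts
    labels <- obj$cells
    counts <- obj$counts
  }
  if (is.data.frame(labels)) {
    lab <- setNames(as.character(labels$cluster), labels$cell)[colnames(counts)]
  } else {
    lab <- as.character(labels)
  }
  keep <- with_seed(derive_seed(seed, "downsample"), {
    unlist(lapply(split(seq_along(lab), lab), function(idx) {
      if (length(idx) <= max_cells) idx else sort(sample(idx, max_cells))
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  out_counts <- counts[, keep, drop = FALSE]
  out_labels <- tibble(cell = colnames(counts)[keep], cluster = lab[keep])
  if (is_sc) {
    structure(list(counts = out_counts, cells = out_labels,
                   cluster_log_means = obj$cluster_log_means),
              class = "sc_counts")
  } else {
    list(counts = out_counts, labels = out_labels)
  }
}
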