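# Readers and writers for the plain-text formats used by the pipeline.
# All tables are TSV with header rows; genomic coordinates are 1-based
# inclusive everywhere except BED output (0-based half-open, per the format).

#' Read and write GWAS summary statistics
#'
#' TSV with columns `SNP`, `CHR`, `BP`, `P`, `N`.
#'
#' @param gwas Tibble with columns `snp`, `chrom`, `pos`, `p`, `n`.
#' @param path File path.
#' @return `read_gwas_tsv()` returns the tibble in internal column names;
#'   `write_gwas_tsv()` returns `path` invisibly.
#' @export
write_gwas_tsv <- function(gwas, path) {
  out <- tibble(SNP = gwas$snp, CHR = gwas$chrom, BP = gwas$pos,
                P = gwas$p, N = gwas$n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  tibble(snp = as.character(df$SNP), chrom = as.character(df$CHR),
         pos = as.integer(df$BP), p = as.numeric(df$P), n = as.numeric(df$N))
}

#' Read and write gene annotation
#'
#' BED-like TSV with 1-based inclusive `start`/`end` and columns `gene`,
#' `symbol`, `chrom`, `start`, `end`, `strand`, `biotype`.
#'
#' @param annotation Gene annotation tibble.
#' @param path File path.
#' @export
write_gene_annotation_tsv <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_annotation_tsv
#' @export
read_gene_annotation_tsv <- function(path) {
  as_tibble(read.delim(path, check.names = FALSE)) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Read and write a cluster-labeled sparse count matrix
#'
#' MatrixMarket sparse counts plus `*.genes.tsv` (gene ids) and
#' `*.cells.tsv` (cell id and cluster label).
#'
#' @param x An `sc_counts` object or genes x cells sparse matrix.
#' @param labels Cell labels tibble (`cell`, `cluster`) when `x` is a bare
#'   matrix.
#' @param prefix Path prefix; writes `<prefix>.mtx`, `<prefix>.genes.tsv`,
#'   `<prefix>.cells.tsv`.
#' @export
write_counts_mtx <- function(x, prefix, labels = NULL) {
  if (inherits(x, "sc_counts")) {
    labels <- x$cells
    x <- x$counts
  }
  Matrix::writeMM(x, paste0(prefix, ".mtx"))
  write.table(tibble(gene = rownames(x)), paste0(prefix, ".genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(labels, paste0(prefix, ".cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix) {
  counts <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  genes <- read.delim(paste0(prefix, ".genes.tsv"))$gene
  cells <- as_tibble(read.delim(paste0(prefix, ".cells.tsv")))
  dimnames(counts) <- list(genes, cells$cell)
  structure(list(counts = counts, cells = cells, cluster_log_means = NULL),
            class = "sc_counts")
}

#' Read and write a genotype reference panel as plain TSV
#'
#' `<prefix>.geno.tsv` holds the individuals x SNPs genotype matrix (header
#' = SNP ids); `<prefix>.snps.tsv` the SNP annotation (`snp`, `chrom`,
#' `pos`, `block`, `maf`, `mac`).
#'
#' @param panel A `reference_panel`.
#' @param prefix Path prefix.
#' @export
write_genotype_tsv <- function(panel, prefix) {
  write.table(panel$genotypes, paste0(prefix, ".geno.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(panel$snps, paste0(prefix, ".snps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(prefix) {
  geno <- as.matrix(read.delim(paste0(prefix, ".geno.tsv"), check.names = FALSE))
  snps <- as_tibble(read.delim(paste0(prefix, ".snps.tsv")))
  structure(list(genotypes = geno, snps = snps), class = "reference_panel")
}

#' Read and write a specificity matrix
#'
#' Genes x cell types TSV; first column `gene`.
#'
#' @param specificity A [compute_specificity()] tibble.
#' @param path File path.
#' @export
write_specificity_tsv <- function(specificity, path) {
  write.table(specificity, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_specificity_tsv
#' @export
read_specificity_tsv <- function(path) {
  df <- as_tibble(read.delim(path, check.names = FALSE))
  structure(df, class = c("specificity", class(tibble())))
}

#' Write gene-level statistics
#'
#' TSV with columns `GENE`, `NSNPS`, `STAT`, `P`, `ZSTAT` followed by the
#' covariate columns.
#'
#' @param gene_stats A `gene_analysis` or its `stats` tibble.
#' @param path File path.
#' @export
write_gene_stats_tsv <- function(gene_stats, path) {
  st <- if (inherits(gene_stats, "gene_analysis")) gene_stats$stats else gene_stats
  out <- st %>%
    rename(GENE = "gene", NSNPS = "n_snps", STAT = "stat", P = "p",
           ZSTAT = "z")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the sparse gene-gene correlation as triplets
#'
#' TSV with columns `GENE1`, `GENE2`, `R` for the nonzero off-diagonal
#' entries.
#'
#' @param corr A [gene_gene_correlation()] matrix.
#' @param path File path.
#' @export
write_gene_corr_triplets <- function(corr, path) {
  tm <- methods::as(methods::as(corr, "generalMatrix"), "TsparseMatrix")
  keep <- tm@i < tm@j
  out <- tibble(GENE1 = rownames(corr)[tm@i[keep] + 1L],
                GENE2 = colnames(corr)[tm@j[keep] + 1L],
                R = tm@x[keep])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cell-type scan results
#'
#' TSV with columns `CELLTYPE`, `BETA`, `SE`, `T`, `P_ONESIDED`, `BONF_SIG`.
#'
#' @param scan A [run_celltype_scan()] result.
#' @param path File path.
#' @export
write_scan_tsv <- function(scan, path) {
  out <- tibble(CELLTYPE = scan$cell_type, BETA = scan$beta, SE = scan$se,
                T = scan$t_stat, P_ONESIDED = scan$p,
                BONF_SIG = scan$bonf_sig)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write selection results and their pairwise audit log
#'
#' Selection TSV: `CELLTYPE`, `STATUS`, `MARGINAL_P`.  Audit TSV: `C1`,
#' `C2`, `P_COND_12`, `P_COND_21`, `PS_12`, `PS_21`, `RULE_FIRED`.
#'
#' @param selection A [select_independent_celltypes()] result.
#' @param path,audit_path File paths.
#' @export
write_selection_tsv <- function(selection, path, audit_path = NULL) {
  out <- tibble(CELLTYPE = selection$selection$cell_type,
                STATUS = selection$selection$status,
                MARGINAL_P = selection$selection$marginal_p)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(audit_path)) {
    a <- selection$audit
    out2 <- tibble(C1 = a$candidate, C2 = a$member,
                   P_COND_12 = a$p_cand_given_member,
                   P_COND_21 = a$p_member_given_cand,
                   PS_12 = a$ps_cand_member, PS_21 = a$ps_member_cand,
                   RULE_FIRED = a$rule)
    write.table(out2, audit_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write SEG annotations as BED
#'
#' Converts the 1-based inclusive intervals of [export_seg_annotations()]
#' to 0-based half-open BED; the cell type goes in the name column.
#'
#' @param seg An [export_seg_annotations()] tibble.
#' @param path File path.
#' @export
write_seg_bed <- function(seg, path) {
  out <- tibble(chrom = seg$chrom, start = seg$start - 1L, end = seg$end,
                name = seg$cell_type)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write ground truth as JSON
#' @param truth A `ground_truth` object.
#' @param path File path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    causal_clusters = truth$causal_clusters,
    causal_genes = truth$causal_genes,
    noncentrality = as.list(truth$noncentrality)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
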