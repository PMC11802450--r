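#' Map SNPs to genes with asymmetric windows
#'
#' A SNP belongs to a gene when it lies within `window_up` bp upstream to
#' `window_down` bp downstream of the gene body.  Windows are strand-aware
#' (upstream of a '-' gene is to its right), 1-based and inclusive at both
#' ends, and clipped at position 1.  A SNP may map to several overlapping
#' genes; genes with no member SNP are dropped with a warning.
#'
#' @param snps Tibble with columns `snp`, `chrom`, `pos`.
#' @param genes Tibble with columns `gene`, `chrom`, `start`, `end` and
#'   optionally `strand` (missing strand is treated as '+').
#' @param window_up Upstream window in bp (default 35 kb).
#' @param window_down Downstream window in bp (default 10 kb).
#' @param quiet Suppress the zero-SNP-gene warning.
#' @return A `gene_models` tibble: `gene`, `chrom`, `window_start`,
#'   `window_end`, `n_snps`, and a list-column `snps` of member SNP ids.
#' @export
#' @examples
#' snps <- tibble::tibble(snp = c("a", "b"), chrom = "chr1",
#'                        pos = c(65000L, 64999L))
#' genes <- tibble::tibble(gene = "g", chrom = "chr1",
#'                         start = 100000L, end = 110000L, strand = "+")
#' annotate_snps_to_genes(snps, genes)$snps[[1]]
annotate_snps_to_genes <- function(snps, genes, window_up = 35000L,
                                   window_down = 10000L, quiet = FALSE) {
  stopifnot(all(c("snp", "chrom", "pos") %in% names(snps)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  bad_chrom <- setdiff(unique(genes$chrom), unique(snps$chrom))
  if (length(bad_chrom)) {
    abort(paste0("chromosome naming inconsistent between genes and SNPs: ",
                 paste(bad_chrom, collapse = ", "),
                 " absent from the SNP table"))
  }
  strand <- if ("strand" %in% names(genes)) {
    ifelse(is.na(genes$strand) | genes$strand == "", "+", genes$strand)
  } else {
    rep("+", nrow(genes))
  }
  ws <- ifelse(strand == "+", genes$start - window_up, genes$start - window_down)
  we <- ifelse(strand == "+", genes$end + window_down, genes$end + window_up)
  ws <- pmax(ws, 1)

  members <- vector("list", nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    si <- which(snps$chrom == ch)
    if (length(si) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = ws[gi], end = we[gi]),
      IRanges::IRanges(start = snps$pos[si], width = 1L))
    hl <- split(si[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits))
    for (nm in names(hl)) {
      idx <- gi[as.integer(nm)]
      members[[idx]] <- snps$snp[sort(hl[[nm]])]
    }
  }
  n_snps <- vapply(members, length, integer(1))
  if (any(n_snps == 0L) && !quiet) {
    warn(sprintf("dropping %d gene(s) with no member SNPs", sum(n_snps == 0L)))
  }
  keep <- n_snps > 0L
  structure(tibble(
    gene = genes$gene[keep],
    chrom = genes$chrom[keep],
    window_start = as.integer(ws[keep]),
    window_end = as.integer(we[keep]),
    n_snps = n_snps[keep],
    snps = members[keep]
  ), class = c("gene_models", class(tibble())))
}
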