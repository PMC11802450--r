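#' Simulate a block-LD genotype reference panel
#'
#' Haplotypes are generated from a Gaussian copula: within each LD block the
#' latent variables are equicorrelated, and each haplotype's latent value is
#' thresholded at the allele-frequency quantile to a 0/1 allele.  Genotypes
#' are the sum of two haplotypes, giving allele counts in `{0, 1, 2}` under
#' Hardy-Weinberg proportions.  SNPs in different blocks are independent.
#' The latent correlation is inflated to `sin(pi/2 * within_block_r)` so the
#' realized genotype correlation lands near the requested value (exact for
#' MAF 0.5; thresholding otherwise attenuates it mildly).
#'
#' SNP positions are evenly spaced along each synthetic chromosome and are
#' strictly increasing; minor-allele frequencies are drawn uniformly from
#' `[0.1, 0.5]`.
#'
#' @param config A [simulation_config()].
#' @return A `reference_panel` list with `genotypes` (individuals x SNPs
#'   integer matrix, SNP ids as column names) and `snps`, a tibble with
#'   columns `snp`, `chrom`, `pos`, `block`, `maf`, `mac`.
#' @export
#' @examples
#' panel <- simulate_reference_panel(
#'   simulation_config(n_haplotypes = 200, n_chromosomes = 1,
#'                     n_blocks_per_chrom = 4, seed = 7))
#' dim(panel$genotypes)
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$within_block_r >= 1) abort("`within_block_r` must be < 1")
  n_ind <- config$n_haplotypes %/% 2L
  k <- config$snps_per_block
  n_blocks <- config$n_blocks_per_chrom
  snps_per_chrom <- n_blocks * k
  genes_per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  chrom_len <- genes_per_chrom * (GENE_LENGTH + GENE_GAP)
  rho <- min(sin(pi / 2 * config$within_block_r), 0.999)

  with_seed(derive_seed(config$seed, "panel"), {
    per_chrom <- lapply(seq_len(config$n_chromosomes), function(ch) {
      pos <- floor(seq(1, chrom_len, length.out = snps_per_chrom))
      pos <- pos + seq_len(snps_per_chrom) - 1L  # enforce strict increase
      maf <- runif(snps_per_chrom, 0.1, 0.5)
      geno <- matrix(0L, n_ind, snps_per_chrom)
      thr <- qnorm(maf)
      for (b in seq_len(n_blocks)) {
        cols <- ((b - 1L) * k + 1L):(b * k)
        for (hap in 1:2) {
          shared <- rnorm(n_ind)
          lat <- sqrt(rho) * shared +
            sqrt(1 - rho) * matrix(rnorm(n_ind * k), n_ind, k)
          geno[, cols] <- geno[, cols] +
            (lat < rep(thr[cols], each = n_ind))
        }
      }
      list(geno = geno,
           snps = tibble(
             snp = sprintf("rs%d_%d", ch, seq_len(snps_per_chrom)),
             chrom = paste0("chr", ch),
             pos = as.integer(pos),
             block = rep(seq_len(n_blocks), each = k),
             maf = maf))
    })
    genotypes <- do.call(cbind, lapply(per_chrom, `[[`, "geno"))
    snps <- bind_rows(lapply(per_chrom, `[[`, "snps"))
    ac <- colSums(genotypes)
    snps$mac <- as.integer(pmin(ac, 2L * n_ind - ac))
    colnames(genotypes) <- snps$snp
    structure(list(genotypes = genotypes, snps = snps),
              class = "reference_panel")
  })
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$snps$chrom))))
  invisible(x)
}
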