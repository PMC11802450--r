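#' Plot a cell-type scan
#'
#' Cell-type index against `-log10` one-sided p, with the Bonferroni
#' threshold as a horizontal line; significant cell types are highlighted.
#'
#' @param object A [run_celltype_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot celltype_scan
#' @export
autoplot.celltype_scan <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- as_tibble(object) %>%
    arrange(.data$cell_type) %>%
    mutate(index = row_number(), neglogp = -log10(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$neglogp,
                                   colour = .data$bonf_sig)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "cell type", y = expression(-log[10](italic(P))),
                  title = "Cell-type association scan") +
    ggplot2::theme_minimal()
}

#' Plot a power curve
#'
#' Bonferroni-significant and selected-independent cell-type counts as a
#' function of GWAS sample size (mean over replicates).
#'
#' @param object A [power_curve_harness()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_curve
#' @export
autoplot.power_curve <- function(object, ...) {
  df <- as_tibble(object) %>%
    group_by(.data$gwas_n) %>%
    summarise(significant = mean(.data$n_significant_celltypes),
              selected = mean(.data$n_selected_independent),
              .groups = "drop") %>%
    tidyr::pivot_longer(c("significant", "selected"),
                        names_to = "measure", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gwas_n, y = .data$count,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "GWAS sample size", y = "cell types",
                  colour = NULL, title = "Detection vs GWAS power") +
    ggplot2::theme_minimal()
}

#' Plot a permutation null
#'
#' Histogram of the one-sided p-values across all permutation instances;
#' a calibrated null is flat.
#'
#' @param object A [permutation_null()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot permutation_summary
#' @export
autoplot.permutation_summary <- function(object, ...) {
  df <- tibble(p = as.numeric(object$p_values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey70", colour = "white") +
    ggplot2::geom_hline(yintercept = nrow(df) * 0.05, linetype = "dashed") +
    ggplot2::labs(x = "one-sided P (permuted gene labels)", y = "count",
                  title = "Permutation null calibration") +
    ggplot2::theme_minimal()
}
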