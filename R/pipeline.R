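#' Pipeline configuration
#'
#' Collects every path and constant the end-to-end analysis needs.  The
#' analysis constants default to the values used throughout the package:
#' 35 kb upstream / 10 kb downstream annotation windows, MHC interval
#' chr6:25000000-34000000, alpha 0.05, gene-z truncation at -3/+6 sd,
#' specificity truncation at +/-5 sd, PS thresholds 0.8 / 0.5 / 0.2 with a
#' rule-2 p bound of 0.05, and downsampling targets 3400 / 340 / 34 cells.
#'
#' @param gwas,annotation,counts_prefix,panel_prefix Input paths (`NULL`
#'   entries must be supplied as in-memory objects to [run_pipeline()]).
#' @param out_dir Output directory (created if missing).
#' @param window_up,window_down Annotation window in bp.
#' @param mhc_chrom,mhc MHC interval to exclude.
#' @param alpha Family-wise error rate.
#' @param ps_high,ps_low,ps_reversal,rule2_alpha Selection thresholds.
#' @param rule2_p `"conditional"` or `"marginal"` (see
#'   [select_independent_celltypes()]).
#' @param downsample_max_cells Downsampling targets (informational; used by
#'   downsampling experiments).
#' @param seed Root seed for stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gwas = NULL, annotation = NULL,
                            counts_prefix = NULL, panel_prefix = NULL,
                            out_dir = tempfile("celltypescan_"),
                            window_up = 35000L, window_down = 10000L,
                            mhc_chrom = "chr6", mhc = c(25000000, 34000000),
                            alpha = 0.05,
                            ps_high = 0.8, ps_low = 0.5, ps_reversal = 0.2,
                            rule2_alpha = 0.05,
                            rule2_p = "conditional",
                            downsample_max_cells = c(3400L, 340L, 34L),
                            seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1,
            ps_reversal <= ps_low, ps_low <= ps_high,
            rule2_alpha > 0, rule2_alpha <= 1)
  structure(list(
    gwas = gwas, annotation = annotation, counts_prefix = counts_prefix,
    panel_prefix = panel_prefix, out_dir = out_dir,
    window_up = as.integer(window_up), window_down = as.integer(window_down),
    mhc_chrom = mhc_chrom, mhc = as.numeric(mhc), alpha = alpha,
    ps_high = ps_high, ps_low = ps_low, ps_reversal = ps_reversal,
    rule2_alpha = rule2_alpha, rule2_p = rule2_p,
    downsample_max_cells = as.integer(downsample_max_cells),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Serialize and restore a pipeline configuration
#'
#' Round-trips the configuration through YAML so every run can be
#' reproduced from the copy written alongside its outputs.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage [", stage, "] failed: ", conditionMessage(e)))
  })
}

#' Run the end-to-end analysis
#'
#' Executes specificity scoring, gene-level association, the cell-type
#' scan, and conditional forward-stepwise selection, logging record counts
#' at stage boundaries and writing every result table plus the
#' configuration to `config$out_dir`.  A rerun with the same configuration
#' and inputs is bit-identical for the deterministic stages.
#'
#' @param config A [pipeline_config()]; its path entries name the input
#'   files, or pass in-memory objects.
#' @param gwas,annotation,counts,panel Optional in-memory inputs (tibble /
#'   `sc_counts` / `reference_panel`) overriding the config paths.
#' @param quiet Suppress stage logging.
#' @return A `pipeline_result` list: `specificity`, `filter_report`,
#'   `gene_analysis`, `scan`, `selection`, `config`, `files`.
#' @export
run_pipeline <- function(config, gwas = NULL, annotation = NULL,
                         counts = NULL, panel = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))

  gwas <- with_stage("input", {
    if (is.null(gwas)) read_gwas_tsv(config$gwas) else gwas
  })
  annotation <- with_stage("input", {
    if (is.null(annotation)) read_gene_annotation_tsv(config$annotation)
    else annotation
  })
  counts <- with_stage("input", {
    if (is.null(counts)) read_counts_mtx(config$counts_prefix) else counts
  })
  say("inputs: %d SNPs, %d genes, %d cells", nrow(gwas), nrow(annotation),
      ncol(counts$counts))

  spec <- with_stage("specificity", {
    expr <- cluster_means(counts)
    expr <- filter_genes(expr, annotation, mhc = config$mhc,
                         mhc_chrom = config$mhc_chrom)
    list(spec = compute_specificity(expr),
         report = gene_filter_report(expr),
         cells = cells_per_cluster(expr))
  })
  say("specificity: %d genes x %d cell types retained",
      nrow(spec$spec), length(celltype_cols(spec$spec)))

  ga <- with_stage("gene_assoc", {
    pan <- if (is.null(panel)) read_genotype_tsv(config$panel_prefix) else panel
    run_gene_analysis(gwas, annotation, pan,
                      window_up = config$window_up,
                      window_down = config$window_down)
  })
  say("gene_assoc: %d genes with statistics", nrow(ga$stats))

  scan <- with_stage("celltype_regression", {
    run_celltype_scan(ga, spec$spec, alpha = config$alpha)
  })
  say("scan: %d of %d cell types Bonferroni-significant",
      sum(scan$bonf_sig), nrow(scan))

  selection <- with_stage("conditional_selection", {
    select_independent_celltypes(
      ga, spec$spec, scan = scan,
      ps_high = config$ps_high, ps_low = config$ps_low,
      ps_reversal = config$ps_reversal, rule2_alpha = config$rule2_alpha,
      rule2_p = config$rule2_p, alpha = config$alpha)
  })
  say("selection: %d independent cell types", length(selection$selected))

  files <- with_stage("output", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- list(
      config = file.path(config$out_dir, "config.yaml"),
      specificity = file.path(config$out_dir, "specificity.tsv"),
      filter_report = file.path(config$out_dir, "gene_filter_report.json"),
      gene_stats = file.path(config$out_dir, "gene_stats.tsv"),
      gene_corr = file.path(config$out_dir, "gene_corr.tsv"),
      scan = file.path(config$out_dir, "celltype_scan.tsv"),
      selection = file.path(config$out_dir, "selection.tsv"),
      audit = file.path(config$out_dir, "selection_audit.tsv"))
    write_pipeline_config(config, f$config)
    write_specificity_tsv(spec$spec, f$specificity)
    jsonlite::write_json(spec$report, f$filter_report, digits = NA)
    write_gene_stats_tsv(ga, f$gene_stats)
    if (!is.null(ga$corr)) write_gene_corr_triplets(ga$corr, f$gene_corr)
    write_scan_tsv(scan, f$scan)
    write_selection_tsv(selection, f$selection, f$audit)
    f
  })

  structure(list(specificity = spec$spec, filter_report = spec$report,
                 cells_per_cluster = spec$cells, gene_analysis = ga,
                 scan = scan, selection = selection, config = config,
                 files = files),
            class = "pipeline_result")
}

#' Run the pipeline on a freshly simulated dataset
#'
#' Generates a complete synthetic study under `config` and runs the
#' analysis stages on it in memory, returning the results together with
#' the planted truth; the workhorse behind the calibration and recovery
#' experiments.
#'
#' @param config A [simulation_config()].
#' @param shared_causal_genes Passed to [make_ground_truth()].
#' @param alpha Family-wise error rate.
#' @param select Also run the stepwise selection.
#' @return List: `dataset`, `specificity`, `gene_analysis`, `scan`,
#'   `selection` (when `select`), `truth`.
#' @export
run_synthetic_pipeline <- function(config, shared_causal_genes = FALSE,
                                   alpha = 0.05, select = TRUE) {
  ds <- simulate_dataset(config, shared_causal_genes = shared_causal_genes)
  expr <- cluster_means(ds$expression)
  expr <- filter_genes(expr, ds$annotation)
  spec <- compute_specificity(expr)
  ga <- run_gene_analysis(ds$gwas, ds$annotation, ds$panel)
  scan <- run_celltype_scan(ga, spec, alpha = alpha)
  selection <- if (select) {
    select_independent_celltypes(ga, spec, scan = scan, alpha = alpha)
  }
  list(dataset = ds, specificity = spec, gene_analysis = ga, scan = scan,
       selection = selection, truth = ds$truth)
}
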