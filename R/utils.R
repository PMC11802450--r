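# Internal helpers shared across modules.

# All stochastic stages consume a seed derived from one root seed so that a
# pipeline run is reproducible stage by stage.  Offsets keep derived seeds
# well inside 32-bit integer range for small root seeds.
derive_seed <- function(seed, stage) {
  offsets <- c(panel = 11L, expression = 23L, gwas = 37L, downsample = 53L,
               permutation = 71L, truth = 89L)
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown seed stage '", stage, "'"))
  }
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  invisible(as.integer(x))
}

check_fraction <- function(x, name, lo = 0, hi = 1, inclusive_hi = FALSE) {
  ok <- length(x) == 1L && is.finite(x) && x >= lo &&
    (if (inclusive_hi) x <= hi else x < hi)
  if (!ok) {
    bound <- if (inclusive_hi) paste0("[", lo, ", ", hi, "]")
             else paste0("[", lo, ", ", hi, ")")
    abort(paste0("`", name, "` must be a single number in ", bound))
  }
  invisible(as.numeric(x))
}

# Column-name helper: cell-type columns of wide gene x cell-type tibbles.
celltype_cols <- function(df) {
  setdiff(names(df), "gene")
}

as_matrix_by_gene <- function(df) {
  m <- as.matrix(df[celltype_cols(df)])
  rownames(m) <- df$gene
  m
}
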