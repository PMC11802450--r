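#' Proportional significance after conditioning
#'
#' `PS = -log(P_conditional) / -log(P_marginal)`: the fraction of a cell
#' type's marginal significance that survives conditioning on another cell
#' type.  The ratio is base-invariant; values near 1 mean the association
#' is independent of the conditioning cell type.
#'
#' @param p_conditional Conditional p-value in `(0, 1]`.
#' @param p_marginal Marginal p-value in `(0, 1)`.
#' @return Nonnegative ratio.
#' @export
#' @examples
#' proportional_significance(1e-8, 1e-10)  # 0.8
proportional_significance <- function(p_conditional, p_marginal) {
  if (any(p_conditional <= 0) || any(p_conditional > 1)) {
    abort("`p_conditional` must lie in (0, 1]")
  }
  if (any(p_marginal <= 0) || any(p_marginal >= 1)) {
    abort("`p_marginal` must lie in (0, 1); PS is undefined at P = 1")
  }
  -log(p_conditional) / -log(p_marginal)
}

#' Pairwise conditional model for two cell types
#'
#' Fits `Z = b0' + P_c1 b1' + P_c2 b2' + C b3' + e` (both specificity
#' columns truncated as in the marginal scan) and reports one-sided
#' p-values for both cell types together with their proportional
#' significance relative to the supplied marginal p-values.
#'
#' @param ctx A scan context from `build_scan_context()` (internal), or
#'   pass `gene_stats`/`specificity`/`correlation` to
#'   [conditional_pair()].
#' @param ct1,ct2 Cell-type column names (`ct1 != ct2`).
#' @param p_marg1,p_marg2 Marginal one-sided p-values from the scan.
#' @return A one-row tibble: `c1`, `c2`, `p_c1_given_c2`, `p_c2_given_c1`,
#'   `ps_c1_c2`, `ps_c2_c1`.
#' @keywords internal
conditional_fit_ctx <- function(ctx, ct1, ct2, p_marg1, p_marg2) {
  if (ct1 == ct2) abort("conditional model needs two distinct cell types")
  s1 <- truncate_specificity(ctx$spec[[ct1]])
  s2 <- truncate_specificity(ctx$spec[[ct2]])
  if (abs(stats::cor(s1, s2)) > 0.9999) {
    abort(paste0("indistinguishable cell types: |corr(", ct1, ", ", ct2,
                 ")| > 0.9999"))
  }
  X2 <- cbind(s2 = s2, ctx$C)
  fit <- gls_fit(ctx$Z, s1, covariates = X2, chol_V = ctx$U)
  co <- fit$coefficients
  p1 <- co$p_one_sided[co$term == "property"]
  p2 <- co$p_one_sided[co$term == "s2"]
  tibble(c1 = ct1, c2 = ct2,
         p_c1_given_c2 = p1, p_c2_given_c1 = p2,
         ps_c1_c2 = proportional_significance(p1, p_marg1),
         ps_c2_c1 = proportional_significance(p2, p_marg2))
}

#' Conditional association of one cell type given another
#'
#' User-facing wrapper around the pairwise conditional model; see
#' [select_independent_celltypes()] for the stepwise procedure built on it.
#'
#' @inheritParams run_celltype_scan
#' @param ct1,ct2 Cell-type column names.
#' @param scan Optional [run_celltype_scan()] result supplying marginal
#'   p-values; recomputed if omitted.
#' @return A one-row tibble as described in `conditional_fit_ctx()`.
#' @export
conditional_pair <- function(gene_stats, specificity, ct1, ct2,
                             correlation = NULL, scan = NULL) {
  ctx <- build_scan_context(gene_stats, specificity, correlation)
  if (is.null(scan)) {
    scan <- run_celltype_scan(gene_stats, specificity, correlation)
  }
  pm <- setNames(scan$p, scan$cell_type)
  conditional_fit_ctx(ctx, ct1, ct2, pm[[ct1]], pm[[ct2]])
}

#' Forward-stepwise selection of relatively independent cell types
#'
#' Starting from the most marginally significant Bonferroni-significant
#' cell type, candidates are visited in order of increasing marginal
#' p-value and added to the selected set S only if, against every member s
#' of S, either (rule 1) both proportional significances are at least
#' `ps_high`, or (rule 2) both lie in `[ps_low, ps_high)` and the rule-2
#' p-value is at most `rule2_alpha`.  When the member's PS given the
#' candidate drops below `ps_reversal` while the candidate's PS given the
#' member does not, the selection order of the pair is reversed: the
#' candidate replaces the member, which is marked explained.  Candidates
#' failing both rules against any member are excluded immediately.  Every
#' pairwise comparison and the rule fired is recorded in an audit table.
#'
#' @inheritParams run_celltype_scan
#' @param scan A [run_celltype_scan()] result; recomputed if omitted.
#' @param ps_high,ps_low,ps_reversal PS thresholds (defaults 0.8, 0.5, 0.2).
#' @param rule2_alpha p-value bound in rule 2 (default 0.05).
#' @param rule2_p Which p-value rule 2 bounds: the candidate's
#'   `"conditional"` p given the member (default; the marginal reading is
#'   vacuous for Bonferroni-significant candidates) or its `"marginal"` p.
#' @param alpha Family-wise error rate defining the significant set.
#' @return A `celltype_selection` object: list with `selection` (tibble
#'   `cell_type`, `status`, `marginal_p`, ordered as visited; status one of
#'   `selected_independent`, `selected_partial`, `excluded_explained`,
#'   `not_significant`), `selected` (ids in selection order), and `audit`
#'   (tibble `candidate`, `member`, conditional Ps, PS values, `rule`).
#' @export
select_independent_celltypes <- function(gene_stats, specificity,
                                         correlation = NULL, scan = NULL,
                                         ps_high = 0.8, ps_low = 0.5,
                                         ps_reversal = 0.2,
                                         rule2_alpha = 0.05,
                                         rule2_p = c("conditional", "marginal"),
                                         alpha = 0.05) {
  rule2_p <- match.arg(rule2_p)
  ctx <- build_scan_context(gene_stats, specificity, correlation)
  if (is.null(scan)) {
    scan <- run_celltype_scan(gene_stats, specificity, correlation,
                              alpha = alpha)
  }
  scan_ord <- scan %>% arrange(.data$p, .data$cell_type)
  sig <- scan_ord %>% filter(.data$bonf_sig)
  pm <- setNames(scan_ord$p, scan_ord$cell_type)

  status <- setNames(rep("not_significant", nrow(scan_ord)),
                     scan_ord$cell_type)
  audit <- list()
  S <- character(0)
  partial <- character(0)

  log_row <- function(cand, memb, pair, rule) {
    audit[[length(audit) + 1L]] <<- tibble(
      candidate = cand, member = memb,
      p_cand_given_member = pair$p_c1_given_c2,
      p_member_given_cand = pair$p_c2_given_c1,
      ps_cand_member = pair$ps_c1_c2,
      ps_member_cand = pair$ps_c2_c1,
      rule = rule)
  }

  for (cand in sig$cell_type) {
    if (length(S) == 0L) {
      S <- cand
      status[cand] <- "selected_independent"
      next
    }
    keep <- TRUE
    used_rule2 <- FALSE
    replaced <- character(0)
    for (memb in S) {
      pair <- tryCatch(
        conditional_fit_ctx(ctx, cand, memb, pm[[cand]], pm[[memb]]),
        error = function(e) NULL)
      if (is.null(pair)) {
        log_row(cand, memb, tibble(p_c1_given_c2 = NA_real_,
                                   p_c2_given_c1 = NA_real_,
                                   ps_c1_c2 = NA_real_, ps_c2_c1 = NA_real_),
                "indistinguishable")
        keep <- FALSE
        break
      }
      ps_cm <- pair$ps_c1_c2   # candidate given member
      ps_mc <- pair$ps_c2_c1   # member given candidate
      if (ps_mc < ps_reversal && ps_cm >= ps_reversal) {
        # the earlier-selected member is explained by the candidate:
        # reverse the selection order for the pair
        log_row(cand, memb, pair, "reversal")
        replaced <- c(replaced, memb)
        next
      }
      if (ps_cm >= ps_high && ps_mc >= ps_high) {
        log_row(cand, memb, pair, "rule1_pass")
        next
      }
      p_rule2 <- if (rule2_p == "conditional") pair$p_c1_given_c2 else pm[[cand]]
      if (ps_cm >= ps_low && ps_cm < ps_high &&
          ps_mc >= ps_low && ps_mc < ps_high &&
          p_rule2 <= rule2_alpha) {
        log_row(cand, memb, pair, "rule2_pass")
        used_rule2 <- TRUE
        next
      }
      log_row(cand, memb, pair, "excluded")
      keep <- FALSE
      break
    }
    if (keep) {
      if (length(replaced)) {
        S <- setdiff(S, replaced)
        status[replaced] <- "excluded_explained"
      }
      S <- c(S, cand)
      status[cand] <- if (used_rule2) "selected_partial" else "selected_independent"
    } else {
      status[cand] <- "excluded_explained"
    }
  }

  selection <- tibble(cell_type = scan_ord$cell_type,
                      status = unname(status[scan_ord$cell_type]),
                      marginal_p = unname(pm[scan_ord$cell_type]))
  structure(list(
    selection = selection,
    selected = S,
    audit = if (length(audit)) bind_rows(audit) else tibble(
      candidate = character(0), member = character(0),
      p_cand_given_member = numeric(0), p_member_given_cand = numeric(0),
      ps_cand_member = numeric(0), ps_member_cand = numeric(0),
      rule = character(0)),
    thresholds = list(ps_high = ps_high, ps_low = ps_low,
                      ps_reversal = ps_reversal, rule2_alpha = rule2_alpha,
                      rule2_p = rule2_p, alpha = alpha)
  ), class = "celltype_selection")
}

#' @export
print.celltype_selection <- function(x, ...) {
  cat(sprintf("<celltype_selection> %d selected of %d significant cell types\n",
              length(x$selected),
              sum(x$selection$status != "not_significant")))
  if (length(x$selected)) cat("  S =", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tidiers
#' @method tidy celltype_selection
#' @export
tidy.celltype_selection <- function(x, ...) x$selection

#' @rdname tidiers
#' @method glance celltype_selection
#' @export
glance.celltype_selection <- function(x, ...) {
  tibble(n_selected = length(x$selected),
         n_significant = sum(x$selection$status != "not_significant"),
         n_comparisons = nrow(x$audit))
}
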