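test_that("gene-z truncation is asymmetric (-3/+6 sd) and idempotent", {
  z <- c(-1, 0, 1, 2)
  expect_equal(truncate_gene_z(z), z)

  z2 <- c(0, 0, 0, 0, 100)
  # mean 20, sd 44.72: 100 < 20 + 6 * 44.72, so unchanged
  expect_equal(truncate_gene_z(z2), z2)
  z3 <- c(rep(0, 100), 1000)
  out3 <- truncate_gene_z(z3)
  expect_equal(out3[101], mean(z3) + 6 * sd(z3))
  # low side clamps at mean - 3 sd
  z4 <- c(rep(0, 20), -1000)
  expect_equal(truncate_gene_z(z4)[21], mean(z4) - 3 * sd(z4))
  # truncation is the identity on vectors already within bounds
  expect_equal(truncate_gene_z(truncate_gene_z(z2)), z2)

  expect_warning(truncate_gene_z(c(1, 1, 1)), "zero variance")
})

test_that("specificity truncation clamps symmetrically at 5 sd", {
  s <- c(rep(0.01, 50), 0.9)
  out <- truncate_specificity(s)
  expect_equal(out[51], mean(s) + 5 * sd(s))
  # identity on columns already within bounds (stats are computed once on
  # the input, so a binding clamp changes them; only no-op cases repeat)
  inb <- c(0.1, 0.2, 0.3, 0.25)
  expect_equal(truncate_specificity(inb), inb)
  expect_warning(truncate_specificity(rep(0.2, 5)), "zero variance")
})

test_that("gls_fit matches the brute-force explicit-inverse oracle", {
  withr::with_seed(5, {
    n <- 10
    X <- cbind(1, runif(n), rnorm(n))
    colnames(X) <- c("(Intercept)", "property", "cov1")
    y <- drop(X %*% c(0.5, 2, -1)) + rnorm(n)

    # identity correlation reduces to OLS
    fit <- gls_fit(y, X[, 2], covariates = X[, 3, drop = FALSE])
    oracle <- brute_gls(y, X, diag(n))
    expect_equal(fit$coefficients$estimate, oracle$beta, tolerance = 1e-8)
    expect_equal(fit$coefficients$std_error, oracle$se, tolerance = 1e-8)
    expect_equal(fit$coefficients$p_one_sided, oracle$p_one_sided,
                 tolerance = 1e-8)

    # banded correlation
    V <- 0.4^abs(outer(1:n, 1:n, "-"))
    fit2 <- gls_fit(y, X[, 2], covariates = X[, 3, drop = FALSE],
                    correlation = V)
    oracle2 <- brute_gls(y, X, V)
    expect_equal(fit2$coefficients$estimate, oracle2$beta, tolerance = 1e-8)
    expect_equal(fit2$coefficients$std_error, oracle2$se, tolerance = 1e-8)
    expect_equal(fit2$coefficients$statistic, oracle2$t, tolerance = 1e-8)
  })
})

test_that("gls_fit handles exact fits, collinearity, and scale equivariance", {
  withr::with_seed(8, {
    p <- runif(20)
    z <- 2 * p + 1
    fit <- gls_fit(z, p)
    co <- fit$coefficients
    expect_equal(co$estimate[co$term == "property"], 2, tolerance = 1e-10)
    expect_lt(co$p_one_sided[co$term == "property"], 1e-12)

    # collinear specificity errors with the offending column named
    expect_error(gls_fit(z, p, covariates = cbind(dup = p)),
                 "collinear")

    # rescaling the property rescales beta by 1/k, leaves t and P unchanged
    zn <- 2 * p + 1 + rnorm(20, 0, 0.3)
    f1 <- gls_fit(zn, p)
    f2 <- gls_fit(zn, p * 10)
    i <- which(f1$coefficients$term == "property")
    expect_equal(f2$coefficients$estimate[i],
                 f1$coefficients$estimate[i] / 10, tolerance = 1e-10)
    expect_equal(f2$coefficients$statistic[i], f1$coefficients$statistic[i],
                 tolerance = 1e-10)
    expect_equal(f2$coefficients$p_one_sided[i],
                 f1$coefficients$p_one_sided[i], tolerance = 1e-12)
  })
})

test_that("an independent property column gives null one-sided p-values", {
  withr::with_seed(12, {
    ps <- replicate(400, {
      z <- rnorm(40)
      fit <- gls_fit(z, runif(40))
      fit$coefficients$p_one_sided[2]
    })
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  })
})

test_that("the cell-type scan flags the planted cluster and applies Bonferroni", {
  res <- run_synthetic_pipeline(tiny_config(seed = 41L), select = FALSE)
  expect_equal(res$scan$cell_type[1], "C1")
  expect_true(res$scan$bonf_sig[1])
  expect_equal(attr(res$scan, "threshold"), 0.05 / 8)
  expect_equal(nrow(res$scan), 8)
  # df accounts for intercept + specificity + covariates
  ncov <- ncol(celltypescan:::build_scan_context(res$gene_analysis,
                                                 res$specificity)$C)
  expect_equal(res$scan$df[1], attr(res$scan, "n_genes") - (ncov + 2))

  # empty gene intersection errors
  spec_other <- res$specificity
  spec_other$gene <- paste0("X_", spec_other$gene)
  expect_error(run_celltype_scan(res$gene_analysis, spec_other),
               "no genes shared")
})

test_that("tidy and glance methods return well-formed tibbles", {
  res <- run_synthetic_pipeline(tiny_config(seed = 43L))
  expect_s3_class(tidy(res$gene_analysis), "tbl_df")
  g <- glance(res$scan)
  expect_equal(g$n_celltypes, 8L)
  expect_s3_class(tidy(res$selection), "tbl_df")
  expect_gte(glance(res$selection)$n_selected, 1L)
  p <- autoplot(res$scan)
  expect_s3_class(p, "ggplot")
})
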