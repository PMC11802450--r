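#' Probit transform of a SNP p-value
#'
#' `z = qnorm(1 - p)`: the z-statistic whose upper tail probability is `p`.
#' p-values are clamped to `[1e-300, 1 - 1e-16]` before the transform so the
#' result is always finite.
#'
#' @param p p-values in `(0, 1]`.
#' @return Standard-normal quantiles.
#' @export
#' @examples
#' snp_z_from_p(c(0.5, 0.05))
snp_z_from_p <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  qnorm(p, lower.tail = FALSE)
}

#' Gene sum-of-squares statistic
#'
#' The gene test statistic is the sum of squared SNP z-statistics over the
#' gene's member SNPs.
#'
#' @param z Numeric vector of SNP z-statistics (at least one).
#' @return `sum(z^2)`.
#' @export
gene_statistic <- function(z) {
  if (length(z) == 0L) abort("a gene needs at least one SNP z-statistic")
  sum(z^2)
}

#' Eigenvalues of the member-SNP LD matrix
#'
#' Computes the eigenvalues (descending) of the Pearson correlation matrix
#' of the member-SNP genotypes; these are the weights of the chi-square
#' mixture null of the gene statistic.  Zero-variance SNPs are removed with
#' a warning before the decomposition.  Negative eigenvalues are clipped at
#' zero, and components below `prune_tol` times the leading eigenvalue are
#' dropped (their count is recorded).
#'
#' @param genotypes Individuals x SNPs genotype matrix for the member SNPs,
#'   or a precomputed correlation matrix (square, unit diagonal).
#' @param prune_tol Relative pruning threshold (default `1e-4`).
#' @return Numeric eigenvalue vector with attributes `n_pruned` (dropped
#'   small components), `n_removed_zero_var`, and `trace` (eigenvalue sum
#'   before pruning, equal to the retained SNP count).
#' @export
ld_eigenvalues <- function(genotypes, prune_tol = 1e-4) {
  is_corr <- is.matrix(genotypes) && nrow(genotypes) == ncol(genotypes) &&
    all(abs(diag(genotypes) - 1) < 1e-8) && all(abs(genotypes) <= 1 + 1e-8)
  if (is_corr) {
    R <- genotypes
    removed <- 0L
  } else {
    v <- apply(genotypes, 2, var)
    removed <- sum(v == 0)
    if (removed > 0L) {
      warn(sprintf("removing %d zero-variance SNP(s) before LD decomposition",
                   removed))
      genotypes <- genotypes[, v > 0, drop = FALSE]
    }
    if (ncol(genotypes) == 0L) abort("no SNP with nonzero variance in panel")
    R <- if (ncol(genotypes) == 1L) matrix(1, 1, 1) else stats::cor(genotypes)
  }
  lam <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  lam <- pmax(lam, 0)
  trace <- sum(lam)
  keep <- lam >= prune_tol * lam[1]
  structure(lam[keep],
            n_pruned = sum(!keep),
            n_removed_zero_var = as.integer(removed),
            trace = trace)
}

#' Tail probability of a weighted chi-square mixture
#'
#' Evaluates `P(sum_j lambda_j Q_j > T)` for independent chi-square(1)
#' variables `Q_j`.  Equal weights use the exact chi-square survival
#' function; otherwise the Imhof numeric inversion is used (absolute
#' tolerance `1e-12`), falling back to the Kuonen saddlepoint approximation
#' in the far tail or on non-convergence (recorded in attribute `method`).
#' Results are floored at `1e-300`.
#'
#' @param T Observed statistic (>= 0).
#' @param lambda Positive mixture weights.
#' @param method `"auto"` (default), or force `"exact"` (requires equal
#'   weights), `"imhof"`, or `"saddlepoint"`.
#' @return p-value in `(0, 1]` with attribute `method`.
#' @export
#' @examples
#' mixture_pvalue(3, c(1, 1))          # exp(-1.5)
#' mixture_pvalue(4.2, c(2.5, 1, 0.5))
mixture_pvalue <- function(T, lambda,
                           method = c("auto", "exact", "imhof", "saddlepoint")) {
  method <- match.arg(method)
  if (!is.finite(T) || T < 0) abort("`T` must be a nonnegative number")
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0L || sum(lambda) <= 0) {
    abort("`lambda` must contain positive weights")
  }
  if (T == 0) return(structure(1, method = "boundary"))

  equalish <- diff(range(lambda)) <= 1e-12 * max(lambda)
  if (method == "exact" && !equalish) {
    abort("method 'exact' requires equal eigenvalues")
  }
  if (method == "auto" && equalish) method <- "exact"

  p <- switch(method,
    exact = pchisq(T / mean(lambda), df = length(lambda), lower.tail = FALSE),
    imhof = ,
    auto = {
      pi_ <- imhof_tail(T, lambda)
      if (is.na(pi_) || pi_ < 1e-9 || pi_ > 1) {
        structure(saddlepoint_tail(T, lambda), method = "saddlepoint")
      } else {
        pi_
      }
    },
    saddlepoint = saddlepoint_tail(T, lambda)
  )
  used <- attr(p, "method")
  if (is.null(used)) used <- method
  structure(min(max(as.numeric(p), 1e-300), 1), method = used)
}

# Imhof (1961) numeric inversion of the characteristic function.
imhof_tail <- function(q, lambda) {
  integrand <- function(u) {
    # u is strictly interior to (0, U) under Gauss-Kronrod nodes
    theta <- -0.5 * q * u
    lrho <- 0
    for (lj in lambda) {
      theta <- theta + 0.5 * atan(lj * u)
      lrho <- lrho + 0.25 * log1p(lj * lj * u * u)
    }
    sin(theta) * exp(-lrho) / u
  }
  # A finite upper limit with a generous subdivision budget is far more
  # accurate here than the infinite-interval transformation.  The integrand
  # decays like u^-(k/2 + 1), so few components need a longer range.
  k <- length(lambda)
  U <- (if (k <= 2) 2e4 else if (k <= 4) 2e3 else 300) / max(mean(lambda), 1)
  # truncation error scales like 1/(q * U^(k/2)); stretch the range when the
  # statistic is small
  U <- U * max(1, 1 / max(q, 0.1))
  res <- tryCatch(
    integrate(integrand, 0, U, abs.tol = 1e-13,
              rel.tol = 1e-12, subdivisions = 50000L),
    error = function(e) NULL)
  if (is.null(res)) return(NA_real_)
  0.5 + res$value / pi
}

# Kuonen (1999) saddlepoint approximation to the survival function.
saddlepoint_tail <- function(q, lambda) {
  m <- sum(lambda)
  if (abs(q - m) < 1e-10 * m) return(0.5)
  hi <- 1 / (2 * max(lambda))
  Kp <- function(z) sum(lambda / (1 - 2 * z * lambda)) - q
  lo <- -1
  while (Kp(lo) > 0) lo <- lo * 2
  zhat <- uniroot(Kp, lower = lo, upper = hi * (1 - 1e-10), tol = 1e-14)$root
  K <- -0.5 * sum(log1p(-2 * zhat * lambda))
  K2 <- sum(2 * lambda^2 / (1 - 2 * zhat * lambda)^2)
  w <- sign(zhat) * sqrt(2 * (zhat * q - K))
  v <- zhat * sqrt(K2)
  if (abs(w) < 1e-8) return(0.5)
  pnorm(w + log(v / w) / w, lower.tail = FALSE)
}
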