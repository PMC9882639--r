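# One-factor confirmatory factor analysis of subconstruct scores (or their
# polychoric correlations), with standard incremental/absolute fit indices.

#' One-factor confirmatory factor analysis
#'
#' For continuous indicators (`estimator = "ml"`) the maximum-likelihood
#' discrepancy `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p` is minimized
#' over loadings and uniquenesses, and `chi^2 = (n - 1) F`. For
#' ordinal/mixed indicators (`estimator = "uls"`) loadings are fit by
#' unweighted least squares to the off-diagonal of the supplied (polychoric)
#' correlation matrix and a residual-based quadratic-form statistic stands in
#' for the chi-square. CFI and TLI are computed against the independence
#' baseline, RMSEA from the noncentrality, SRMR on the correlation metric.
#' Three indicators give a just-identified model (df = 0, perfect fit,
#' flagged); two are rejected as under-identified.
#'
#' @param x either a numeric score matrix (persons x indicators) or a
#'   correlation/covariance matrix (with `n` supplied).
#' @param n sample size (required when `x` is a correlation matrix).
#' @param estimator `"ml"` or `"uls"`.
#' @return list of class `CfaFit`: `loadings` (standardized), `chisq`, `df`,
#'   `cfi`, `rmsea`, `srmr`, `estimator`, `converged`, `flags`.
#' @export
oneFactorCfa <- function(x, n = NULL, estimator = c("ml", "uls")) {
  estimator <- match.arg(estimator)
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-10) {
    S <- x
    if (is.null(n)) .stopf("n is required when supplying a correlation matrix")
  } else {
    n <- nrow(x)
    S <- cor(x, use = "pairwise.complete.obs")
  }
  p <- ncol(S)
  if (p < 3) .stopf("a one-factor model needs at least 3 indicators")
  flags <- character(0)
  ev1 <- eigen(S, symmetric = TRUE)
  lam0 <- ev1$vectors[, 1] * sqrt(ev1$values[1])
  if (mean(lam0) < 0) lam0 <- -lam0
  lam0 <- pmin(pmax(lam0, -0.95), 0.95)
  if (estimator == "ml") {
    fobj <- function(par) {
      lam <- par[1:p]; psi <- exp(par[(p + 1):(2 * p)])
      Sigma <- tcrossprod(lam) + diag(psi)
      dec <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(dec)) return(1e10)
      logdet <- 2 * sum(log(diag(dec)))
      logdet + sum(diag(chol2inv(dec) %*% S)) - determinant(S)$modulus[1] - p
    }
    opt <- nlminb(c(lam0, log(pmax(1 - lam0^2, 0.1))), fobj,
                  control = list(iter.max = 500))
    lam <- opt$par[1:p]; psi <- exp(opt$par[(p + 1):(2 * p)])
    Sigma <- tcrossprod(lam) + diag(psi)
    Fmin <- opt$objective
    conv <- opt$convergence == 0 || Fmin < 1e-8
    chisq <- (n - 1) * Fmin
    df <- p * (p + 1) / 2 - 2 * p
    # independence baseline (correlation metric: diag already free)
    F0 <- -determinant(S)$modulus[1]
    chisq0 <- (n - 1) * F0
    df0 <- p * (p - 1) / 2
    # standardized solution for reporting
    d <- sqrt(diag(Sigma))
    lamStd <- lam / d
  } else {
    fobj <- function(lam) {
      R <- S - tcrossprod(lam)
      sum(R[lower.tri(R)]^2)
    }
    opt <- nlminb(lam0, fobj, lower = -0.999, upper = 0.999,
                  control = list(iter.max = 500))
    lamStd <- opt$par
    Sigma <- tcrossprod(lamStd); diag(Sigma) <- 1
    conv <- opt$convergence == 0
    df <- p * (p - 1) / 2 - p
    chisq <- n * 2 * opt$objective  # residual-based quadratic form
    chisq0 <- n * sum(S[lower.tri(S)]^2)
    df0 <- p * (p - 1) / 2
  }
  if (any(abs(lamStd) > 1)) flags <- c(flags, "Heywood case (|loading| > 1)")
  if (!conv) flags <- c(flags, "optimizer did not converge")
  resid <- cov2cor(S) - cov2cor(Sigma)
  srmr <- sqrt(mean(resid[lower.tri(resid)]^2))
  if (df <= 0) {
    flags <- c(flags, "just-identified model (df = 0): perfect fit")
    out <- list(loadings = lamStd, chisq = 0, df = df, cfi = 1, rmsea = 0,
                srmr = srmr, estimator = estimator, converged = conv,
                flags = flags)
    return(structure(out, class = "CfaFit"))
  }
  cfi <- 1 - max(chisq - df, 0) / max(chisq - df, chisq0 - df0, 1e-12)
  rmsea <- sqrt(max(0, (chisq - df) / (df * (n - 1))))
  structure(list(loadings = lamStd, chisq = chisq, df = df,
                 cfi = min(max(cfi, 0), 1), rmsea = rmsea, srmr = srmr,
                 estimator = estimator, converged = conv, flags = flags),
            class = "CfaFit")
}

#' @export
print.CfaFit <- function(x, ...) {
  cat(sprintf("CfaFit (%s): chisq(%d) = %.1f, CFI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$estimator, x$df, x$chisq, x$cfi, x$rmsea, x$srmr))
  cat("  loadings:", paste(sprintf("%.3f", x$loadings), collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
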