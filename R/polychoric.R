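# Two-stage (thresholds-then-rho) polychoric correlation estimation for
# ordinal questionnaire items under pairwise deletion.

# Gauss-Legendre nodes/weights on [-1, 1] (computed once at load time via the
# Golub-Welsch eigenvalue method).
.glRule <- local({
  n <- 64L
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
})

# Standard bivariate normal CDF P(X <= a, Y <= b; rho), vectorized over a and
# b (equal length), scalar rho. Computed by Gauss-Legendre quadrature of
# phi(x) * Phi((b - rho x)/sqrt(1 - rho^2)) over x in (-Inf, a].
.pbvn <- function(a, b, rho) {
  stopifnot(length(a) == length(b))
  out <- numeric(length(a))
  if (abs(rho) >= 1) {  # degenerate comonotone/antimonotone limits
    s <- sign(rho)
    return(if (s > 0) pnorm(pmin(a, b)) else pmax(0, pnorm(a) + pnorm(b) - 1))
  }
  lo <- -8.5
  hi <- pmin(a, 8.5)
  deg <- hi <= lo | b == -Inf
  fin <- !deg
  if (any(fin)) {
    av <- hi[fin]; bv <- b[fin]
    half <- (av - lo) / 2
    mid <- (av + lo) / 2
    # nodes matrix: length(av) x nGL
    x <- outer(half, .glRule$nodes) + mid
    s <- sqrt(1 - rho^2)
    integ <- dnorm(x) * pnorm((bv - rho * x) / s)
    out[fin] <- half * as.vector(integ %*% .glRule$weights)
  }
  out[a == Inf & b != -Inf] <- pnorm(b[a == Inf & b != -Inf])
  out[b == Inf & a != Inf] <- pnorm(a[b == Inf & a != Inf])
  out[a == Inf & b == Inf] <- 1
  pmin(pmax(out, 0), 1)
}

#' Estimate normal-metric thresholds for one ordinal item
#'
#' Threshold k is the standard-normal quantile of the cumulative proportion
#' of responses at or below category k. Categories never observed yield
#' infinite thresholds; an item with all responses in a single category is
#' flagged degenerate (no finite thresholds).
#'
#' @param x integer codes in `1..nCategories` (NAs dropped).
#' @param nCategories number of response categories.
#' @return numeric vector of `nCategories - 1` thresholds (attribute
#'   `degenerate` set when none is finite).
#' @export
estimateThresholds <- function(x, nCategories = 5L) {
  x <- x[!is.na(x)]
  if (!length(x)) .stopf("cannot estimate thresholds from an all-missing column")
  counts <- tabulate(x, nbins = nCategories)
  cum <- cumsum(counts)[-nCategories] / length(x)
  tau <- qnorm(cum)
  attr(tau, "degenerate") <- !any(is.finite(tau))
  tau
}

# negative log-likelihood of the two-way table under bivariate normality with
# margins fixed at (tx, ty)
.polyNegLL <- function(rho, tab, tx, ty) {
  kx <- length(tx) + 1L; ky <- length(ty) + 1L
  ax <- c(-Inf, tx, Inf); ay <- c(-Inf, ty, Inf)
  iu <- rep(2:(kx + 1L), times = ky); ju <- rep(2:(ky + 1L), each = kx)
  P <- .pbvn(ax[iu], ay[ju], rho) - .pbvn(ax[iu - 1L], ay[ju], rho) -
       .pbvn(ax[iu], ay[ju - 1L], rho) + .pbvn(ax[iu - 1L], ay[ju - 1L], rho)
  P <- pmax(matrix(P, kx, ky), 1e-12)
  -sum(tab * log(P))
}

#' Polychoric correlation of two ordinal items
#'
#' Two-stage maximum likelihood: thresholds are fixed from the univariate
#' margins of the pairwise-complete observations, then the latent correlation
#' maximizes the bivariate-normal cell likelihood by bounded one-dimensional
#' optimization. Estimates are guarded at |rho| <= 0.999 so downstream factor
#' routines keep finite information.
#'
#' @param x,y integer codes in `1..nCategories`.
#' @param nCategories number of response categories.
#' @return list with `rho`, `converged`, `n` (pairwise n), and the two
#'   threshold vectors.
#' @export
polychoricPair <- function(x, y, nCategories = 5L) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0L)
    return(list(rho = NA_real_, converged = FALSE, n = 0L,
                thresholds = list(NULL, NULL)))
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, converged = FALSE, n = n,
                thresholds = list(NULL, NULL)))
  tx <- estimateThresholds(x, nCategories)
  ty <- estimateThresholds(y, nCategories)
  txf <- tx[is.finite(tx)]; tyf <- ty[is.finite(ty)]
  tab <- table(factor(x, levels = seq_len(nCategories)),
               factor(y, levels = seq_len(nCategories)))
  # drop unobserved categories (infinite thresholds collapse their cells)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  opt <- optimize(.polyNegLL, interval = c(-0.999, 0.999), tab = tab,
                  tx = txf, ty = tyf, tol = 1e-6)
  rho <- opt$minimum
  if (abs(rho) > 0.998) rho <- sign(rho) * 0.999  # boundary guard
  list(rho = rho, converged = TRUE, n = n, thresholds = list(tx, ty))
}

#' Pairwise polychoric correlation matrix
#'
#' Applies [polychoricPair()] to every item pair under pairwise deletion
#' (planned missingness by questionnaire version makes listwise deletion
#' untenable), reports the smallest eigenvalue, and optionally repairs a
#' non-positive-semi-definite matrix by eigenvalue clipping (flagged).
#'
#' @param x a [SensoryExperiment-class] or a persons-by-items integer matrix.
#' @param items optional subset of item identifiers (columns).
#' @param nCategories response categories per item.
#' @param repair project a non-PSD pairwise matrix to the nearest PSD
#'   correlation matrix.
#' @return a [PolychoricResult-class].
#' @export
polychoricMatrix <- function(x, items = NULL, nCategories = 5L, repair = TRUE) {
  if (is(x, "SensoryExperiment")) x <- t(responses(x))
  x <- as.matrix(x)
  if (!is.null(items)) x <- x[, items, drop = FALSE]
  p <- ncol(x)
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("item", seq_len(p))
  R <- diag(p); dimnames(R) <- list(ids, ids)
  N <- matrix(0L, p, p, dimnames = dimnames(R))
  diag(N) <- colSums(!is.na(x))
  conv <- matrix(TRUE, p, p, dimnames = dimnames(R))
  thr <- lapply(seq_len(p), function(j) {
    xi <- x[, j]
    if (all(is.na(xi))) .stopf("item '%s' is all-missing", ids[j])
    estimateThresholds(xi, nCategories)
  })
  names(thr) <- ids
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    pr <- polychoricPair(x[, i], x[, j], nCategories)
    R[i, j] <- R[j, i] <- pr$rho
    N[i, j] <- N[j, i] <- pr$n
    conv[i, j] <- conv[j, i] <- pr$converged
  }
  Rcomplete <- R
  Rcomplete[is.na(Rcomplete)] <- 0  # flagged pairs contribute no association
  ev <- eigen(Rcomplete, symmetric = TRUE, only.values = TRUE)$values
  repaired <- FALSE
  if (min(ev) < -1e-10 && repair) {
    Rcomplete <- .nearPSDcor(Rcomplete)
    repaired <- TRUE
  }
  new("PolychoricResult", rho = Rcomplete, thresholds = thr, pairwiseN = N,
      converged = conv, psdRepaired = repaired, minEigenvalue = min(ev))
}

#' Write a polychoric correlation matrix to CSV
#'
#' @param poly a [PolychoricResult-class].
#' @param path CSV path; item IDs form the header and first column.
#' @export
writePolychoric <- function(poly, path) {
  write.csv(polyCor(poly), path)
  invisible(path)
}
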