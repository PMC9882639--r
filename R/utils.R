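# Internal helpers shared across modules.

#' @importFrom methods new is validObject slot
#' @importFrom stats dnorm pnorm qnorm plogis optimize nlminb rnorm runif rbinom
#'   quantile median sd var cor rgamma setNames complete.cases
#' @importFrom utils head read.csv write.csv
#' @importFrom tools md5sum
NULL

.MODALITIES <- c("Auditory", "Visual", "Tactile", "Olfactory", "Gustatory",
                 "OralTactile", "Movement")
.PATTERNS <- c("HYPER", "HYPO", "SEEK")

# Logistic-to-probit bridging constant used to move between GRM slopes and
# standardized factor loadings.
.D_CONST <- 1.702

#' Fixed quadrature grid over the latent trait
#'
#' Equally spaced nodes with standard-normal weights, normalized to sum to one.
#' Used by every marginal-likelihood computation in the package so that results
#' are deterministic given the data.
#'
#' @param nNodes number of nodes.
#' @param bounds range of the grid.
#' @return list with `nodes` and `weights`.
#' @keywords internal
quadratureGrid <- function(nNodes = 49L, bounds = c(-6, 6)) {
  nodes <- seq(bounds[1], bounds[2], length.out = nNodes)
  w <- dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

# log(sum(exp(x))) rowwise over a matrix, guarded against underflow
.rowLogSumExp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Nearest positive semi-definite correlation matrix by eigenvalue clipping,
# rescaled back to unit diagonal.
.nearPSDcor <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  S <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(S))
  R2 <- S / tcrossprod(d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}

# shortest highest-density interval from posterior draws: the narrowest
# window of ceiling(prob * n) order statistics
.hdiFromDraws <- function(draws, prob = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- min(n, max(2L, ceiling(prob * n)))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1L])
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
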