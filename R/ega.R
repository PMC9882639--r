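# Exploratory graph analysis: a regularized partial-correlation network
# estimated by the graphical lasso over a log-spaced penalty grid, model
# selected by EBIC, and item communities detected by Walktrap random walks.

# Graphical lasso (Friedman-Hastie-Tibshirani blockwise coordinate descent).
# S: covariance/correlation matrix; rho: scalar L1 penalty. Returns the
# estimated covariance W and precision Theta.
.glasso <- function(S, rho, maxIter = 100L, tol = 1e-4) {
  p <- ncol(S)
  W <- S + rho * diag(p)
  B <- matrix(0, p, p)  # regression coefficients per column
  if (p == 1) return(list(W = W, Theta = 1 / W))
  for (it in seq_len(maxIter)) {
    Wold <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[idx, j]
      # lasso subproblem by coordinate descent:
      # min 0.5 b' W11 b - s12' b + rho |b|_1
      for (cd in seq_len(50L)) {
        bOld <- beta
        for (k in seq_len(p - 1L)) {
          r <- s12[k] - sum(W11[k, -k] * beta[-k])
          beta[k] <- sign(r) * max(abs(r) - rho, 0) / W11[k, k]
        }
        if (max(abs(beta - bOld)) < tol * 1e-2) break
      }
      B[idx, j] <- beta
      W[idx, j] <- W[j, idx] <- W11 %*% beta
    }
    if (mean(abs(W - Wold)) < tol * mean(abs(S - diag(diag(S))))) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    denom <- W[j, j] - sum(W[idx, j] * B[idx, j])
    Theta[j, j] <- 1 / denom
    Theta[idx, j] <- -B[idx, j] / denom
  }
  Theta <- (Theta + t(Theta)) / 2
  list(W = W, Theta = Theta)
}

#' Exploratory graph analysis of an item correlation matrix
#'
#' Fits graphical-lasso partial-correlation networks over a log-spaced
#' penalty grid, selects the penalty by the extended BIC with parameter
#' `gamma`, and assigns items to communities with the Walktrap algorithm
#' (random walks on absolute partial-correlation edge weights). An empty
#' selected graph leaves each item in its own community and sets a flag.
#'
#' @param poly a [PolychoricResult-class] or correlation matrix (PSD;
#'   repaired upstream if needed).
#' @param n sample size behind the correlations.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param nPenalty number of penalty values on the grid.
#' @param steps Walktrap random-walk length (default 4).
#' @return list of class `EgaResult`: `network` (partial correlations),
#'   `communities` (integer assignment), `nCommunities`, `penalty`, `ebic`
#'   (selection path), `emptyGraph`.
#' @export
ega <- function(poly, n, gamma = 0.5, nPenalty = 20L, steps = 4L) {
  S <- if (is(poly, "PolychoricResult")) polyCor(poly) else as.matrix(poly)
  p <- ncol(S)
  ids <- colnames(S)
  if (is.null(ids)) ids <- paste0("item", seq_len(p))
  rhoMax <- max(abs(S[upper.tri(S)]))
  if (rhoMax < 1e-8) {  # no association at all: empty network
    pcor <- matrix(0, p, p, dimnames = list(ids, ids))
    return(structure(list(network = pcor, communities = seq_len(p),
                          items = ids, nCommunities = p, penalty = NA_real_,
                          ebic = numeric(0), emptyGraph = TRUE),
                     class = "EgaResult"))
  }
  grid <- exp(seq(log(rhoMax), log(rhoMax / 100), length.out = nPenalty))
  best <- NULL; bestEbic <- Inf
  ebicPath <- numeric(nPenalty)
  for (i in seq_along(grid)) {
    fit <- .glasso(S, grid[i])
    Theta <- fit$Theta
    E <- sum(abs(Theta[upper.tri(Theta)]) > 1e-8)
    dec <- tryCatch(chol(Theta), error = function(e) NULL)
    if (is.null(dec)) { ebicPath[i] <- Inf; next }
    logdet <- 2 * sum(log(diag(dec)))
    ll <- (n / 2) * (logdet - sum(S * Theta))
    ebicPath[i] <- -2 * ll + E * log(n) + 4 * E * gamma * log(p)
    if (ebicPath[i] < bestEbic) { bestEbic <- ebicPath[i]; best <- fit
                                  bestRho <- grid[i] }
  }
  Theta <- best$Theta
  pcor <- -Theta / sqrt(tcrossprod(diag(Theta)))
  diag(pcor) <- 0
  pcor[abs(pcor) < 1e-8] <- 0
  dimnames(pcor) <- list(ids, ids)
  emptyGraph <- all(pcor == 0)
  if (emptyGraph) {
    comm <- seq_len(p)
  } else {
    gAdj <- abs(pcor)
    gr <- igraph::graph_from_adjacency_matrix(gAdj, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    wt <- igraph::cluster_walktrap(gr, steps = steps,
                                   weights = igraph::E(gr)$weight)
    comm <- igraph::membership(wt)
    # isolated vertices get their own community already via walktrap
  }
  names(comm) <- ids
  structure(list(network = pcor, communities = as.integer(comm),
                 items = ids, nCommunities = length(unique(comm)),
                 penalty = bestRho, ebic = ebicPath, emptyGraph = emptyGraph),
            class = "EgaResult")
}

#' @export
print.EgaResult <- function(x, ...) {
  cat("EgaResult:", x$nCommunities, "communities",
      if (x$emptyGraph) "(empty graph)" else "", "\n")
  for (k in sort(unique(x$communities)))
    cat(sprintf("  [%d] %s\n", k,
                paste(x$items[x$communities == k], collapse = ", ")))
  invisible(x)
}
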