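# Hierarchical item clustering guided by internal-consistency (alpha) and
# worst-split-half (beta) reliability, in the ICLUST tradition: clusters
# merge in order of composite similarity, and a merge is accepted only when
# the merged cluster's beta does not fall below the weaker candidate's beta.

# unit-weight composite correlation between two clusters from a correlation
# matrix
.compositeCor <- function(R, a, b) {
  covAB <- sum(R[a, b])
  varA <- sum(R[a, a]); varB <- sum(R[b, b])
  covAB / sqrt(varA * varB)
}

.alphaOf <- function(R, idx) {
  k <- length(idx)
  if (k < 2) return(NA_real_)
  rbar <- (sum(R[idx, idx]) - k) / (k * (k - 1))
  k * rbar / (1 + (k - 1) * rbar)
}

#' Hierarchical item clustering (ICLUST)
#'
#' Agglomerative clustering of items on a (polychoric) correlation matrix.
#' At each step the two most similar clusters (by unit-weight composite
#' correlation) merge; the merged cluster's beta -- the Spearman-Brown
#' stepped-up correlation between the two merging halves, the worst split
#' at that node -- may not fall more than `betaSlack` below the better
#' candidate's beta, and the inter-composite correlation must be positive.
#' Alpha (standardized) and beta are recorded at every accepted node. Single
#' items carry no internal-consistency evidence (beta `NA`), so item-item
#' merges are governed by positivity of the correlation alone.
#'
#' @param poly a [PolychoricResult-class] or plain correlation matrix.
#' @param items optional subset of items.
#' @param betaSlack how far the merged cluster's beta may fall below the
#'   better candidate's beta before the merge is refused (default 0.15);
#'   guards the cluster's internal consistency while permitting the gradual
#'   beta decline that accompanies legitimate growth.
#' @return list of class `ClusterTree`: `clusters` (final partition as item
#'   index vectors), `history` (merge record with alpha/beta), `labels`.
#' @export
iclust <- function(poly, items = NULL, betaSlack = 0.15) {
  R <- if (is(poly, "PolychoricResult")) polyCor(poly) else as.matrix(poly)
  if (!is.null(items)) R <- R[items, items]
  p <- ncol(R)
  if (p < 2) .stopf("iclust needs at least 2 items")
  labels <- colnames(R)
  if (is.null(labels)) labels <- paste0("item", seq_len(p))
  clusters <- as.list(seq_len(p))
  betas <- rep(NA_real_, p)
  history <- data.frame()
  step <- 0L
  repeat {
    k <- length(clusters)
    if (k < 2) break
    # similarity between all current cluster pairs
    sim <- matrix(-Inf, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      sim[i, j] <- .compositeCor(R, clusters[[i]], clusters[[j]])
    ord <- order(sim[upper.tri(sim)], decreasing = TRUE)
    pairs <- which(upper.tri(sim), arr.ind = TRUE)[ord, , drop = FALSE]
    merged <- FALSE
    for (rw in seq_len(nrow(pairs))) {
      i <- pairs[rw, 1]; j <- pairs[rw, 2]
      rAB <- sim[i, j]
      if (!is.finite(rAB) || rAB <= 0) break  # sorted: nothing positive left
      betaNew <- 2 * rAB / (1 + rAB)
      betaRef <- suppressWarnings(max(c(betas[i], betas[j]), na.rm = TRUE))
      if (is.finite(betaRef) && betaNew < betaRef - betaSlack) next
      idx <- c(clusters[[i]], clusters[[j]])
      step <- step + 1L
      history <- rbind(history, data.frame(
        step = step,
        items = paste(labels[idx], collapse = ","),
        size = length(idx), similarity = rAB,
        alpha = .alphaOf(R, idx), beta = betaNew))
      clusters[[i]] <- idx
      betas[i] <- betaNew
      clusters[[j]] <- NULL
      betas <- betas[-j]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  structure(list(clusters = clusters, history = history, labels = labels,
                 betas = betas), class = "ClusterTree")
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat("ClusterTree:", length(x$clusters), "final cluster(s)\n")
  for (i in seq_along(x$clusters))
    cat(sprintf("  [%d] %s (beta = %s)\n", i,
                paste(x$labels[x$clusters[[i]]], collapse = ", "),
                ifelse(is.na(x$betas[i]), "-", sprintf("%.3f", x$betas[i]))))
  invisible(x)
}
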