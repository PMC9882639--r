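# Iterative single-subconstruct scale refinement: cluster, fit, evaluate
# against the retention criteria, drop the locally worst item, and fall back
# to a designated single item when no acceptable scale remains.

#' Retention criteria for a subconstruct scale
#'
#' The psychometric bar a candidate scale must clear: limited-information
#' TLI above `tliMin`, RMSEA below `rmseaMax`, SRMR below `srmrMax` (with a
#' stricter cutoff for exactly three items, where TLI/RMSEA are undefined),
#' marginal reliability above `rhoMin`, and total-score omega above
#' `omegaMin`.
#'
#' @param tliMin,rmseaMax,srmrMax,srmrMax3Item,rhoMin,omegaMin thresholds.
#' @return list of class `RefinementCriteria`.
#' @export
refinementCriteria <- function(tliMin = 0.97, rmseaMax = 0.089,
                               srmrMax = 0.05, srmrMax3Item = 0.033,
                               rhoMin = 0.7, omegaMin = 0.7) {
  vals <- c(tliMin, rmseaMax, srmrMax, srmrMax3Item, rhoMin, omegaMin)
  if (any(vals <= 0 | vals >= 1)) .stopf("all thresholds must lie in (0, 1)")
  structure(list(tliMin = tliMin, rmseaMax = rmseaMax, srmrMax = srmrMax,
                 srmrMax3Item = srmrMax3Item, rhoMin = rhoMin,
                 omegaMin = omegaMin), class = "RefinementCriteria")
}

#' Evaluate retention criteria from fit and reliability values
#'
#' Pure rule check, usable on reported values as well as on fitted models.
#' With exactly three items only SRMR (at the stricter cutoff) and the two
#' reliability criteria apply; TLI/RMSEA are undefined for a just-identified
#' model.
#'
#' @param values list/fit with elements `tli`, `rmsea`, `srmr`, `rhoXX`,
#'   `omegaT` (missing or `NA` entries are skipped where undefined).
#' @param criteria a [refinementCriteria()].
#' @param nItems number of items on the scale.
#' @return list with `pass` and a named logical vector `checks`.
#' @export
evaluateCriteria <- function(values, criteria = refinementCriteria(),
                             nItems) {
  checks <- c(
    tli = if (nItems > 3 && !is.null(values$tli) && !is.na(values$tli))
      values$tli > criteria$tliMin else NA,
    rmsea = if (nItems > 3 && !is.null(values$rmsea) && !is.na(values$rmsea))
      values$rmsea < criteria$rmseaMax else NA,
    srmr = values$srmr < (if (nItems == 3) criteria$srmrMax3Item
                          else criteria$srmrMax),
    rhoXX = values$rhoXX > criteria$rhoMin,
    omegaT = values$omegaT > criteria$omegaMin)
  list(pass = all(checks, na.rm = TRUE), checks = checks)
}

#' Refine a candidate item set into a unidimensional subconstruct scale
#'
#' Implements the iterative refinement loop: (1) cluster the candidate items
#' on their polychoric correlations with [iclust()] and keep the largest
#' cluster with at least three items; (2) fit a unidimensional graded
#' response model; (3) evaluate the retention criteria (SRMR cutoff switches
#' at exactly three items); (4) on failure, remove the item with the largest
#' maximum absolute residual polychoric correlation (ties broken by the
#' lowest loading) and repeat; (5) stop when the criteria pass, or declare a
#' single-item fallback when fewer than three items remain or a removal
#' fails to improve SRMR. The fallback item is the bank's `most_global`
#' annotation for the candidate pool (an explicit data annotation standing
#' in for expert judgment), when available.
#'
#' @param x responses ([SensoryExperiment-class] or persons-by-items matrix).
#' @param items candidate item identifiers.
#' @param criteria a [refinementCriteria()].
#' @param bank optional [ItemBank-class] supplying the `most_global`
#'   fallback annotation.
#' @param nCategories response categories.
#' @param tol,maxCycles EM controls passed to [fitGrm()].
#' @return list of class `RefinementResult`: `decision` (`"scale"` or
#'   `"single_item"`), `items` (final scale or the fallback item), `fit`
#'   (final [GrmSolution-class] or `NULL`), and `trace` (a data.frame, one
#'   row per step, with criterion values, action and reason).
#' @export
refineScale <- function(x, items, criteria = refinementCriteria(),
                        bank = NULL, nCategories = 5L, tol = 1e-4,
                        maxCycles = 200L) {
  if (length(items) == 0) .stopf("empty candidate item set")
  if (is(x, "SensoryExperiment")) x <- t(responses(x))
  x <- as.matrix(x)[, items, drop = FALSE]
  n <- nrow(x)
  trace <- data.frame()
  note <- function(step, items, action, reason, vals = list()) {
    rbind(trace, data.frame(
      step = step, items = paste(items, collapse = ","),
      nItems = length(items),
      srmr = if (is.null(vals$srmr)) NA else vals$srmr,
      tli = if (is.null(vals$tli) || is.na(vals$tli)) NA else vals$tli,
      rmsea = if (is.null(vals$rmsea) || is.na(vals$rmsea)) NA else vals$rmsea,
      rhoXX = if (is.null(vals$rhoXX)) NA else vals$rhoXX,
      omegaT = if (is.null(vals$omegaT)) NA else vals$omegaT,
      action = action, reason = reason))
  }
  fallback <- function(pool, reason, step) {
    fb <- NA_character_
    if (!is.null(bank)) {
      it <- as.data.frame(itemInfo(bank))
      cand <- it$item_id[it$most_global & it$item_id %in% items]
      if (length(cand)) fb <- cand[1]
    }
    trace <<- note(step, if (is.na(fb)) character(0) else fb,
                   "single_item_fallback", reason)
    structure(list(decision = "single_item", items = fb, fit = NULL,
                   trace = trace), class = "RefinementResult")
  }
  current <- colnames(x)
  step <- 0L
  if (length(current) < 3)
    return(fallback(current, "fewer than three candidate items", 1L))
  if (length(current) > 3) {
    # step 1: hierarchical clustering; keep the largest cluster of >= 3
    # items (with exactly three candidates there is nothing to prune)
    poly <- polychoricMatrix(x[, current, drop = FALSE],
                             nCategories = nCategories)
    tree <- iclust(poly)
    sizes <- lengths(tree$clusters)
    big <- which(sizes >= 3)
    step <- step + 1L
    if (!length(big))
      return(fallback(current, "no cluster with three or more items", step))
    keep <- tree$labels[tree$clusters[[big[which.max(sizes[big])]]]]
    if (length(keep) < length(current))
      trace <- note(step, setdiff(current, keep), "cluster_prune",
                    "outside the largest ICLUST cluster")
    current <- keep
  }
  prevSrmr <- Inf
  repeat {
    step <- step + 1L
    poly <- polychoricMatrix(x[, current, drop = FALSE],
                             nCategories = nCategories)
    fit <- fitGrm(x[, current, drop = FALSE], nCategories = nCategories,
                  tol = tol, maxCycles = maxCycles)
    li <- limitedInformationFit(fit, poly, n)
    fit@fit <- li[c("srmr", "rmsea", "tli", "df")]
    vals <- list(srmr = li$srmr, rmsea = li$rmsea, tli = li$tli,
                 rhoXX = fit@rhoXX, omegaT = fit@omegaTotal)
    ev <- evaluateCriteria(vals, criteria, length(current))
    if (ev$pass) {
      trace <- note(step, current, "retain_scale", "criteria met", vals)
      return(structure(list(decision = "scale", items = current, fit = fit,
                            trace = trace), class = "RefinementResult"))
    }
    failed <- names(ev$checks)[!is.na(ev$checks) & !ev$checks]
    if (length(current) <= 3)
      return(fallback(current, paste("criteria failed at three items:",
                                     paste(failed, collapse = ",")), step))
    if (li$srmr >= prevSrmr)
      return(fallback(current, "item removal no longer improves SRMR", step))
    prevSrmr <- li$srmr
    # remove the item with the worst local misfit
    resid <- abs(li$residuals); diag(resid) <- 0
    worst <- apply(resid, 1, max)
    cand <- which(worst == max(worst))
    if (length(cand) > 1)  # tie-break: lowest loading
      cand <- cand[which.min(abs(fit@loadings[cand, "lambdaG"]))]
    drop <- current[cand]
    trace <- note(step, drop, "remove_item",
                  sprintf("largest max |residual| = %.3f (criteria failed: %s)",
                          max(worst), paste(failed, collapse = ",")), vals)
    current <- setdiff(current, drop)
  }
}

#' @export
print.RefinementResult <- function(x, ...) {
  cat("RefinementResult:", x$decision, "->",
      paste(x$items, collapse = ", "), "\n")
  print(x$trace[, c("step", "nItems", "srmr", "rhoXX", "omegaT", "action")])
  invisible(x)
}

#' Write a refinement trace to JSON
#'
#' @param result a `RefinementResult` from [refineScale()].
#' @param path output path.
#' @export
writeRefinementTrace <- function(result, path) {
  jsonlite::write_json(list(decision = result$decision, items = result$items,
                            trace = result$trace),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
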