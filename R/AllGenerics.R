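#' @include AllClasses.R
NULL

#' Accessors for sensefactor classes
#'
#' Small accessor generics for the package's S4 containers: item metadata and
#' crosswalk of an [ItemBank], the ordinal response codes, study labels and
#' item identifiers of a [SensoryExperiment], and the correlation matrix of a
#' [PolychoricResult].
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("itemInfo", function(x) standardGeneric("itemInfo"))
#' @rdname accessors
#' @export
setGeneric("sourceCodes", function(x) standardGeneric("sourceCodes"))
#' @rdname accessors
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))
#' @rdname accessors
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))
#' @rdname accessors
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))
#' @rdname accessors
#' @export
setGeneric("polyCor", function(x) standardGeneric("polyCor"))
#' @rdname accessors
#' @export
setGeneric("itemThresholds", function(x) standardGeneric("itemThresholds"))
#' @rdname accessors
#' @export
setGeneric("standardizedLoadings", function(x) standardGeneric("standardizedLoadings"))

#' @rdname accessors
#' @export
setMethod("itemInfo", "ItemBank", function(x) x@items)
#' @rdname accessors
#' @export
setMethod("sourceCodes", "ItemBank", function(x) x@sourceCodes)
#' @rdname accessors
#' @export
setMethod("responses", "SensoryExperiment", function(x) assay(x, "responses"))
#' @rdname accessors
#' @export
setMethod("studyId", "SensoryExperiment", function(x) colData(x)$study_id)
#' @rdname accessors
#' @export
setMethod("itemIds", "SensoryExperiment", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("itemIds", "ItemBank", function(x) x@items$item_id)
#' @rdname accessors
#' @export
setMethod("polyCor", "PolychoricResult", function(x) x@rho)
#' @rdname accessors
#' @export
setMethod("itemThresholds", "PolychoricResult", function(x) x@thresholds)
#' @rdname accessors
#' @export
setMethod("standardizedLoadings", "GrmSolution", function(x) x@loadings)

setMethod("show", "ItemBank", function(object) {
  it <- object@items
  cat("ItemBank with", nrow(it), "items,", nrow(object@sourceCodes),
      "source codes\n")
  tab <- table(it$response_pattern, it$modality)
  print(tab)
  invisible(NULL)
})

setMethod("show", "PolychoricResult", function(object) {
  cat("PolychoricResult:", nrow(object@rho), "items; min eigenvalue",
      signif(object@minEigenvalue, 4),
      if (object@psdRepaired) "(PSD-repaired)" else "", "\n")
  invisible(NULL)
})

setMethod("show", "GrmSolution", function(object) {
  spec <- stats::na.omit(unique(object@structure))
  cat(sprintf("GrmSolution: %d items, %s model, n = %d\n",
              length(object@items),
              if (length(spec)) sprintf("bifactor (%d specific factors)", length(spec))
              else "unidimensional", object@nPersons))
  cat(sprintf("  logLik = %.2f after %d EM cycles (%s)\n", object@logLik,
              object@nCycles,
              if (object@converged) "converged" else "NOT converged"))
  if (length(object@rhoXX)) cat(sprintf("  marginal reliability = %.3f\n", object@rhoXX))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  invisible(NULL)
})

setMethod("show", "BifactorIndexSet", function(object) {
  cat(sprintf("BifactorIndexSet: omegaT = %.3f, omegaH = %.3f, ECV_G = %.3f\n",
              object@omegaT, object@omegaH, object@ecvG))
  if (nrow(object@subscales)) print(as.data.frame(object@subscales))
  invisible(NULL)
})

setMethod("show", "IdaEffectSummary", function(object) {
  if (object@refused) {
    cat("IdaEffectSummary:", object@outcome, "~", object@correlate,
        "REFUSED:", object@reason, "\n")
  } else {
    cat(sprintf("IdaEffectSummary: %s ~ %s (%s = %.3f, 95%% HDI [%.3f, %.3f])\n",
                object@outcome, object@correlate, object@effectType,
                object@median, object@hdi[1], object@hdi[2]))
    cat(sprintf("  P_ROPE = %.3f, log BF_ROPE = %.2f -> %s\n",
                object@pRope, object@logBfRope, object@category))
  }
  invisible(NULL)
})
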