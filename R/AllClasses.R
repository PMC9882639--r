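#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData colData<-
NULL

#' ItemBank: harmonized sensory item definitions
#'
#' Holds the item-level taxonomy used throughout the pipeline: one row per
#' harmonized item with its sensory modality (Auditory, Visual, Tactile,
#' Olfactory, Gustatory, OralTactile, Movement), response pattern (HYPER,
#' HYPO, SEEK), number of ordinal categories, and flags marking single-item
#' indicators and the "most global" item used as a single-item fallback when a
#' subconstruct scale cannot be retained. A crosswalk table maps each
#' harmonized item to its source-instrument codes (e.g. the same question
#' appearing on both the Sensory Profile and the Sensory Experiences
#' Questionnaire). Instruments listed in `reverseInstruments` are scored in
#' the opposite direction and are flipped during harmonization.
#'
#' @slot items DataFrame with columns `item_id`, `modality`,
#'   `response_pattern`, `n_categories`, `single_item_indicator`,
#'   `most_global`.
#' @slot sourceCodes DataFrame with columns `instrument`, `code`, `item_id`.
#' @slot reverseInstruments character vector of instruments whose raw codes
#'   run in the reverse direction (scores of 1 mean most frequent).
#' @exportClass ItemBank
setClass("ItemBank",
  representation(items = "DataFrame", sourceCodes = "DataFrame",
                 reverseInstruments = "character"))

setValidity("ItemBank", function(object) {
  it <- object@items
  sc <- object@sourceCodes
  msgs <- character()
  need <- c("item_id", "modality", "response_pattern", "n_categories",
            "single_item_indicator", "most_global")
  if (!all(need %in% colnames(it)))
    return(paste("items must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(it$item_id))
    msgs <- c(msgs, paste("duplicate item_id:",
                          paste(unique(it$item_id[duplicated(it$item_id)]), collapse = ", ")))
  bad <- setdiff(unique(it$modality), .MODALITIES)
  if (length(bad)) msgs <- c(msgs, paste("unknown modality:", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(it$response_pattern), .PATTERNS)
  if (length(bad)) msgs <- c(msgs, paste("unknown response_pattern:", paste(bad, collapse = ", ")))
  if (any(it$n_categories < 2)) msgs <- c(msgs, "n_categories must be >= 2")
  if (nrow(sc)) {
    key <- paste(sc$instrument, sc$code)
    if (anyDuplicated(key))
      msgs <- c(msgs, paste("duplicate source code:",
                            paste(unique(key[duplicated(key)]), collapse = ", ")))
    orphan <- setdiff(unique(sc$item_id), it$item_id)
    if (length(orphan))
      msgs <- c(msgs, paste("source codes refer to unknown item_id:",
                            paste(orphan, collapse = ", ")))
  }
  uncovered <- setdiff(it$item_id, sc$item_id)
  if (length(uncovered))
    msgs <- c(msgs, paste("items without any source code:",
                          paste(uncovered, collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SensoryExperiment: ordinal item responses across pooled studies
#'
#' A `SummarizedExperiment` subclass holding the harmonized persons-by-items
#' ordinal response codes (items as rows, persons as columns, assay
#' `"responses"`). Observed codes lie in `1..n_categories`; `NA` marks planned
#' missingness from instrument coverage. `colData` carries `study_id`,
#' `instruments` (comma-separated list of questionnaires the person
#' completed), and optionally `age` plus correlate variables. `rowData`
#' carries item metadata copied from the [ItemBank].
#'
#' @exportClass SensoryExperiment
setClass("SensoryExperiment", contains = "SummarizedExperiment")

setValidity("SensoryExperiment", function(object) {
  if (!"responses" %in% names(assays(object)))
    return("assay 'responses' is required")
  m <- assay(object, "responses")
  nc <- if ("n_categories" %in% colnames(rowData(object)))
    rowData(object)$n_categories else rep(5L, nrow(m))
  obs <- !is.na(m)
  if (any(m[obs] < 1) || any((m < 1 | m > nc)[obs]))
    return("observed response codes must lie in 1..n_categories")
  if (any(m[obs] != round(m[obs])))
    return("response codes must be integers")
  if (!"study_id" %in% colnames(colData(object)))
    return("colData must contain study_id")
  TRUE
})

#' PolychoricResult: thresholds and polychoric correlations for ordinal items
#'
#' @slot rho symmetric items-by-items polychoric correlation matrix with unit
#'   diagonal; entries estimated pairwise under pairwise deletion.
#' @slot thresholds list of per-item threshold vectors on the standard-normal
#'   metric (length `n_categories - 1`; unobserved categories give infinite
#'   thresholds).
#' @slot pairwiseN matrix of pairwise complete sample sizes.
#' @slot converged logical matrix of per-pair optimizer convergence.
#' @slot psdRepaired TRUE when the pairwise matrix was projected to the
#'   nearest positive semi-definite correlation matrix.
#' @slot minEigenvalue smallest eigenvalue of the raw pairwise matrix.
#' @exportClass PolychoricResult
setClass("PolychoricResult",
  representation(rho = "matrix", thresholds = "list", pairwiseN = "matrix",
                 converged = "matrix", psdRepaired = "logical",
                 minEigenvalue = "numeric"))

setValidity("PolychoricResult", function(object) {
  R <- object@rho
  if (nrow(R) != ncol(R)) return("rho must be square")
  if (max(abs(R - t(R))) > 1e-8) return("rho must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) return("rho must have unit diagonal")
  if (any(abs(R) > 1 + 1e-8, na.rm = TRUE)) return("rho entries must lie in [-1, 1]")
  for (tau in object@thresholds) {
    fin <- tau[is.finite(tau)]
    if (length(fin) > 1 && any(diff(fin) <= 0))
      return("finite thresholds must be strictly increasing")
  }
  TRUE
})

#' GrmSolution: fitted (bi)factor graded response model
#'
#' Item parameters are stored in the logistic slope--intercept metric: for an
#' item with K categories, the probability of responding above category k is
#' `plogis(aG * thetaG + aS * thetaS + c_k)` with strictly decreasing
#' intercepts `c_1 > ... > c_{K-1}`. Standardized loadings are derived via
#' the 1.702 logistic-probit bridge.
#'
#' @slot items character vector of item identifiers.
#' @slot slopesG numeric general-factor slopes.
#' @slot slopesS numeric specific-factor slopes (0 for general-only items).
#' @slot intercepts list of per-item intercept vectors (decreasing).
#' @slot structure character vector naming each item's specific factor
#'   (`NA` for general-only items; all `NA` for a unidimensional model).
#' @slot loadings matrix with columns `lambdaG`, `lambdaS`.
#' @slot logLik observed-data marginal log-likelihood.
#' @slot logLikHistory per-cycle log-likelihood trace (non-decreasing).
#' @slot nPersons number of persons contributing.
#' @slot fit list of limited-information fit indices (may be empty).
#' @slot rhoXX marginal reliability of the (general-factor) EAP score.
#' @slot omegaTotal model-based total-score reliability.
#' @slot converged logical EM convergence flag.
#' @slot nCycles EM cycles used.
#' @slot flags character vector of warnings (e.g. Heywood-like slopes).
#' @exportClass GrmSolution
setClass("GrmSolution",
  representation(items = "character", slopesG = "numeric", slopesS = "numeric",
                 intercepts = "list", structure = "character",
                 loadings = "matrix", logLik = "numeric",
                 logLikHistory = "numeric", nPersons = "integer", fit = "list",
                 rhoXX = "numeric", omegaTotal = "numeric",
                 converged = "logical", nCycles = "integer",
                 flags = "character"))

setValidity("GrmSolution", function(object) {
  p <- length(object@items)
  if (length(object@slopesG) != p || length(object@slopesS) != p ||
      length(object@intercepts) != p || length(object@structure) != p)
    return("parameter slots must match the number of items")
  for (cc in object@intercepts)
    if (length(cc) > 1 && any(diff(cc) >= 0))
      return("intercepts must be strictly decreasing")
  spec <- stats::na.omit(unique(object@structure))
  for (s in spec)
    if (sum(object@structure == s, na.rm = TRUE) < 2)
      return(sprintf("specific factor '%s' has fewer than 2 items", s))
  TRUE
})

#' BifactorIndexSet: reliability and explained-common-variance indices
#'
#' Computed from standardized bifactor loadings: omega total/hierarchical for
#' the full scale, omega subscale/hierarchical-subscale per specific factor,
#' the general factor's explained common variance overall, per subscale, and
#' per item, and item communalities.
#'
#' @slot omegaT,omegaH numeric scalars for the total score.
#' @slot ecvG general-factor explained common variance.
#' @slot subscales DataFrame with per-subscale `omegaS`, `omegaHS`, `ecvG`,
#'   `ecvSS`.
#' @slot itemTable DataFrame with per-item `lambdaG`, `lambdaS`, `h2`, `iecv`.
#' @exportClass BifactorIndexSet
setClass("BifactorIndexSet",
  representation(omegaT = "numeric", omegaH = "numeric", ecvG = "numeric",
                 subscales = "DataFrame", itemTable = "DataFrame"))

setValidity("BifactorIndexSet", function(object) {
  it <- object@itemTable
  if (nrow(it)) {
    if (any(it$iecv < -1e-8 | it$iecv > 1 + 1e-8)) return("I-ECV must lie in [0, 1]")
    if (max(abs(it$h2 - (it$lambdaG^2 + it$lambdaS^2))) > 1e-6)
      return("h2 must equal lambdaG^2 + lambdaS^2")
  }
  ss <- object@subscales
  if (nrow(ss) && max(abs(ss$ecvG + ss$ecvSS - 1)) > 1e-6)
    return("per-subscale ECV_G + ECV_SS must equal 1")
  TRUE
})

#' IdaEffectSummary: posterior summary of one correlate association
#'
#' Posterior effect size (correlation r for continuous correlates, Cohen's d
#' for binary ones) from the Bayesian random-effects integrative model, with
#' the 95% highest-density interval, probability of practical equivalence,
#' log ROPE Bayes factor, five-way evidence category, heterogeneity summaries
#' (tau^2, I^2, ICC) and the 95% prediction interval for a new study.
#'
#' @exportClass IdaEffectSummary
setClass("IdaEffectSummary",
  representation(outcome = "character", correlate = "character",
                 effectType = "character", median = "numeric",
                 hdi = "numeric", pRope = "numeric", logBfRope = "numeric",
                 category = "character", tau2 = "numeric", tau = "numeric",
                 i2 = "numeric", icc = "numeric",
                 predictionInterval = "numeric", rhat = "numeric",
                 nCases = "integer", nDraws = "integer", refused = "logical",
                 reason = "character"))

setValidity("IdaEffectSummary", function(object) {
  if (object@refused) return(TRUE)
  if (object@pRope < 0 || object@pRope > 1) return("pRope must lie in [0, 1]")
  if (length(object@hdi) == 2 &&
      (object@hdi[1] > object@median || object@median > object@hdi[2]))
    return("median must lie inside the HDI")
  TRUE
})
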