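# Synthetic multi-study generator. Emulates the statistical structure the
# pipeline assumes -- ordinal items generated by a bifactor GRM, pooled
# studies with between-study mean shifts, instrument-dependent planned
# missingness, and correlates with known population effect sizes -- so every
# stage is testable without any deposited data.

#' Reference bifactor loading tables
#'
#' Packaged standardized loading matrices for the three caregiver-reported
#' sensory response patterns (hyperreactivity, hyporeactivity, seeking) from
#' the consortium bifactor analyses of the Sensory Profile and Sensory
#' Experiences Questionnaire item pool. These serve as generating structures
#' for the synthetic-data module and as inputs to [bifactorIndices()].
#'
#' @param construct one of `"hyper"`, `"hypo"`, `"seek"`.
#' @return list with `items`, `lambdaG`, `lambdaS`, `structure`.
#' @export
referenceLoadings <- function(construct = c("hyper", "hypo", "seek")) {
  construct <- match.arg(construct)
  path <- system.file("extdata", paste0("loadings_", construct, ".tsv"),
                      package = "sensefactor", mustWork = TRUE)
  df <- read.csv(path, sep = "\t", check.names = FALSE,
                 na.strings = "NA")
  list(items = df$item_id, lambdaG = df$lambdaG, lambdaS = df$lambdaS,
       structure = as.character(df$specific))
}

#' Specification for the synthetic multi-study generator
#'
#' Defaults encode the pooled-study conditions the pipeline is designed for:
#' around a dozen contributing studies of widely varying size, five-category
#' ordinal items driven by a bifactor graded response model (default
#' generating loadings: the hyperreactivity reference table), evenly spaced
#' category thresholds, moderate between-study shifts in the general trait,
#' and instrument-coverage patterns that impose structural missingness.
#'
#' @param nStudies number of studies (default 12).
#' @param nPerStudy per-study sample sizes; a single value recycles, `NULL`
#'   draws log-uniform sizes between 30 and 1300.
#' @param loadings list with `items`, `lambdaG`, `lambdaS`, `structure`
#'   (see [referenceLoadings()]).
#' @param thresholds latent-response thresholds per item, default evenly
#'   spaced on \[-2, 2\].
#' @param studySd SD of between-study shifts of the general trait mean
#'   (default 0.4, putting roughly 10-20 percent of trait variance between
#'   studies).
#' @param coverage list of item-index vectors, one pattern per study (recycled);
#'   `NULL` means all items observed everywhere.
#' @param correlates data.frame with columns `name`, `type`
#'   (`"continuous"`/`"binary"`), `effect` (population r or d against the
#'   general trait), `tau1` (between-study SD of the effect).
#' @param nCategories ordinal categories (default 5).
#' @return list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nStudies = 12L, nPerStudy = NULL,
                          loadings = referenceLoadings("hyper"),
                          thresholds = NULL, studySd = 0.4, coverage = NULL,
                          correlates = NULL, nCategories = 5L) {
  if (!is.null(correlates))
    if (any(abs(correlates$effect) >= 1 & correlates$type == "continuous"))
      .stopf("infeasible target correlation (|r| >= 1)")
  if (is.null(thresholds))
    thresholds <- seq(-2, 2, length.out = nCategories - 1L)
  structure(list(nStudies = as.integer(nStudies), nPerStudy = nPerStudy,
                 loadings = loadings, thresholds = thresholds,
                 studySd = studySd, coverage = coverage,
                 correlates = correlates, nCategories = as.integer(nCategories)),
            class = "SyntheticSpec")
}

# draw ordinal responses from the GRM implied by standardized loadings and
# probit thresholds, at latent values theta (n x (1 + S))
.drawResponses <- function(lambdaG, lambdaS, structure, thetaG, thetaS,
                           thresholds, nCategories) {
  n <- length(thetaG)
  p <- length(lambdaG)
  sl <- loadingsToSlopes(lambdaG, lambdaS)
  psi <- sqrt(1 - (lambdaG^2 + lambdaS^2))
  out <- matrix(NA_integer_, n, p)
  for (j in seq_len(p)) {
    lin <- sl[j, "aG"] * thetaG
    if (!is.na(structure[j])) lin <- lin + sl[j, "aS"] * thetaS[, structure[j]]
    tau <- if (is.matrix(thresholds)) thresholds[j, ] else thresholds
    cvec <- -.D_CONST * tau / psi[j]
    # cumulative P(X > k) at each person's latent position
    Pstar <- plogis(outer(lin, cvec, "+"))
    u <- runif(n)
    out[, j] <- 1L + rowSums(u < Pstar)
  }
  out
}

#' Generate a synthetic multi-study sensory dataset
#'
#' Latent general and specific traits are independent standard normals (the
#' general trait additionally shifted by a study effect); item categories are
#' drawn from the bifactor GRM category probabilities; correlates are built
#' as linear combinations of the general trait and independent noise
#' calibrated so the population effect equals the target (per-study effects
#' vary around the target with SD `tau1`); missingness follows the study's
#' instrument-coverage pattern. Fully reproducible given `seed`.
#'
#' @param spec a [syntheticSpec()].
#' @param seed integer master seed.
#' @return list of class `SyntheticDataset` with elements `se` (a
#'   [SensoryExperiment-class]), `correlates` (person-level data.frame), and
#'   `truth` (latent traits, generating parameters, per-study effects).
#' @export
simulateSensoryData <- function(spec = syntheticSpec(), seed = 1L) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(seed)
  L <- spec$loadings
  p <- length(L$lambdaG)
  S <- unique(L$structure[!is.na(L$structure)])
  nPer <- spec$nPerStudy
  if (is.null(nPer)) {
    nPer <- round(exp(runif(spec$nStudies, log(30), log(1300))))
  } else if (length(nPer) == 1L) {
    nPer <- rep(nPer, spec$nStudies)
  }
  stopifnot(length(nPer) == spec$nStudies)
  n <- sum(nPer)
  study <- rep(paste0("study", seq_len(spec$nStudies)), nPer)
  shift <- rnorm(spec$nStudies, 0, spec$studySd)
  thetaG <- rnorm(n) + shift[match(study, unique(study))]
  thetaS <- matrix(rnorm(n * length(S)), n, length(S),
                   dimnames = list(NULL, S))
  corr <- NULL
  effTruth <- list()
  if (!is.null(spec$correlates)) {
    thetaGc <- thetaG - shift[match(study, unique(study))]  # unit-variance part
    corr <- data.frame(person_id = sprintf("p%05d", seq_len(n)),
                       study_id = study)
    for (i in seq_len(nrow(spec$correlates))) {
      nm <- spec$correlates$name[i]
      eff <- spec$correlates$effect[i]
      tau1 <- spec$correlates$tau1[i]
      effS <- eff + rnorm(spec$nStudies, 0, tau1)
      es <- effS[match(study, unique(study))]
      if (spec$correlates$type[i] == "continuous") {
        noiseSd <- sqrt(pmax(1 - es^2, 0.01))
        corr[[nm]] <- es * thetaGc + noiseSd * rnorm(n)
      } else {
        # binary group with latent mean difference d (in SD units)
        grp <- rbinom(n, 1L, 0.5)
        corr[[nm]] <- grp
        # shift the general trait by d for the flagged group, recentered
        thetaGc <- thetaGc + es * (grp - 0.5)
        thetaGc <- thetaGc / sd(thetaGc)
      }
      effTruth[[nm]] <- list(effect = eff, perStudy = effS)
    }
    thetaG <- thetaGc + shift[match(study, unique(study))]
  }
  m <- .drawResponses(L$lambdaG, L$lambdaS, L$structure, thetaG, thetaS,
                      spec$thresholds, spec$nCategories)
  # structural missingness by study coverage pattern
  if (!is.null(spec$coverage)) {
    pat <- rep(seq_along(spec$coverage), length.out = spec$nStudies)
    for (s in seq_len(spec$nStudies)) {
      rows <- which(study == paste0("study", s))
      hide <- setdiff(seq_len(p), spec$coverage[[pat[s]]])
      if (length(hide)) m[rows, hide] <- NA_integer_
    }
  }
  pid <- sprintf("p%05d", seq_len(n))
  rownames(m) <- pid; colnames(m) <- L$items
  se <- SummarizedExperiment(
    assays = list(responses = t(m)),
    rowData = DataFrame(item_id = L$items, n_categories = spec$nCategories,
                        specific = L$structure, row.names = L$items),
    colData = DataFrame(study_id = study, instruments = "synthetic",
                        row.names = pid))
  se <- as(se, "SensoryExperiment")
  structure(list(se = se, correlates = corr,
                 truth = list(thetaG = thetaG, thetaS = thetaS,
                              lambdaG = L$lambdaG, lambdaS = L$lambdaS,
                              structure = L$structure, studyShift = shift,
                              nPerStudy = nPer, effects = effTruth,
                              seed = seed)),
            class = "SyntheticDataset")
}

#' Deterministic fixture bundle for unit tests
#'
#' Builds, from one seed, the small deterministic objects the test-suite
#' shares: a toy six-item bank, a planted three-cluster correlation matrix
#' with its known partition, a null-effect multi-study correlate set, and the
#' three reference loading tables.
#'
#' @param seed integer seed.
#' @return named list of fixtures.
#' @export
makeFixtureSuite <- function(seed = 1L) {
  set.seed(seed)
  bankItems <- data.frame(
    item_id = paste0("aud_hyper_", 1:6),
    modality = "Auditory", response_pattern = "HYPER",
    n_categories = 5L, single_item_indicator = FALSE,
    most_global = c(TRUE, rep(FALSE, 5)))
  bankSrc <- data.frame(
    instrument = rep(c("SP1", "SEQ3"), each = 6),
    code = c(paste0("Q", 1:6), paste0("Q", 11:16)),
    item_id = rep(bankItems$item_id, 2))
  toyBank <- ItemBank(bankItems, bankSrc)
  # planted 3 x 2-item cluster population correlation matrix
  R <- matrix(0.1, 6, 6)
  blocks <- list(1:2, 3:4, 5:6)
  for (b in blocks) R[b, b] <- 0.7
  diag(R) <- 1
  dimnames(R) <- list(paste0("v", 1:6), paste0("v", 1:6))
  nullCorr <- simulateSensoryData(
    syntheticSpec(nStudies = 6L, nPerStudy = 80L,
                  loadings = referenceLoadings("hypo"),
                  correlates = data.frame(name = "null_x", type = "continuous",
                                          effect = 0, tau1 = 0)),
    seed = seed + 1L)
  list(toyBank = toyBank, plantedClusters = list(R = R, partition = blocks),
       nullEffect = nullCorr,
       loadings = list(hyper = referenceLoadings("hyper"),
                       hypo = referenceLoadings("hypo"),
                       seek = referenceLoadings("seek")))
}
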