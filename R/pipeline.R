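# Orchestration of the full analysis for one response-pattern construct:
# per-modality scale refinement, supra-modal structure evaluation (CFA of
# subconstruct scores, EGA, bifactor GRM, bifactor indices and
# interpretability verdicts), EAP score emission for interpretable
# (sub)constructs only, and the correlate IDA stage.

#' Configuration for a pipeline run
#'
#' @param data a `SyntheticDataset` from [simulateSensoryData()], or a list
#'   with elements `se` (a [SensoryExperiment-class] whose `rowData` has a
#'   `specific` column) and optionally `correlates` (person-level
#'   data.frame).
#' @param constructName label for reports.
#' @param criteria a [refinementCriteria()].
#' @param correlates data.frame with `name` and `type`
#'   (`"continuous"`/`"binary"`) selecting correlate columns to model;
#'   `NULL` skips the IDA stage.
#' @param idaDraws,idaChains,idaWarmup,minCases IDA sampler settings.
#' @param grmTol,grmMaxCycles EM controls for all model fits.
#' @param refit `"auto"` re-fits the supra-modal CFA without single-item
#'   indicators when the initial model fits poorly (the option generalizing
#'   the seeking-domain re-fit rule); `"never"` disables it.
#' @param seed master seed threaded into every stochastic stage.
#' @param outDir artifact directory (created if missing).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(data, constructName = "construct",
                           criteria = refinementCriteria(),
                           correlates = NULL, idaDraws = 2000L,
                           idaChains = 4L, idaWarmup = 1000L,
                           minCases = 100L, grmTol = 1e-4,
                           grmMaxCycles = 200L,
                           refit = c("auto", "never"), seed = 1L,
                           outDir = tempfile("sensefactor_run_")) {
  refit <- match.arg(refit)
  se <- if (inherits(data, "SyntheticDataset")) data$se else data$se
  if (!"specific" %in% colnames(rowData(se)))
    .stopf("rowData(se) must carry a 'specific' column naming each item's subconstruct")
  structure(list(data = data, constructName = constructName,
                 criteria = criteria, correlates = correlates,
                 idaDraws = as.integer(idaDraws),
                 idaChains = as.integer(idaChains),
                 idaWarmup = as.integer(idaWarmup),
                 minCases = as.integer(minCases), grmTol = grmTol,
                 grmMaxCycles = as.integer(grmMaxCycles), refit = refit,
                 seed = as.integer(seed), outDir = outDir),
            class = "PipelineConfig")
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes refinement, structure evaluation, score emission and (optionally)
#' the correlate IDA stage, writing JSON/CSV artifacts plus a manifest with
#' the seed, package version and md5 hashes of every artifact. Stage
#' failures are caught: partial results are preserved alongside a
#' machine-readable error record.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) list with the stage results and the manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  se <- config$data$se
  x <- t(responses(se))
  specAssign <- setNames(as.character(rowData(se)$specific), rownames(se))
  groups <- split(names(specAssign), specAssign)
  singles <- names(specAssign)[is.na(specAssign)]
  errors <- list()
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  ## stage 1: per-subconstruct refinement
  refinement <- stage("refinement", {
    out <- lapply(names(groups), function(g) {
      refineScale(x, groups[[g]], criteria = config$criteria,
                  nCategories = max(rowData(se)$n_categories),
                  tol = config$grmTol, maxCycles = config$grmMaxCycles)
    })
    names(out) <- names(groups)
    out
  })
  retained <- list()
  if (!is.null(refinement)) {
    for (g in names(refinement))
      if (refinement[[g]]$decision == "scale")
        retained[[g]] <- refinement[[g]]$items
    .writeJson(lapply(refinement, function(r)
      list(decision = r$decision, items = r$items, trace = r$trace)),
      file.path(config$outDir, "refinement.json"))
  }
  ## stage 2: structure evaluation
  structureRes <- stage("structure", {
    scaleItems <- unlist(retained, use.names = FALSE)
    stopifnot(length(retained) >= 2)
    eapMat <- sapply(names(retained), function(g) {
      fit <- refinement[[g]]$fit
      eapScores(fit, x[, fit@items, drop = FALSE])$theta
    })
    cfaScores <- oneFactorCfa(cbind(eapMat,
                                    if (length(singles))
                                      x[, singles, drop = FALSE]),
                              estimator = "ml")
    cfaUsed <- "scores_plus_singles"
    if (config$refit == "auto" &&
        (cfaScores$cfi < 0.95 || cfaScores$rmsea > 0.06) &&
        ncol(eapMat) >= 3) {
      cfaScores <- oneFactorCfa(eapMat, estimator = "ml")
      cfaUsed <- "scores_only"
    }
    bifItems <- c(scaleItems, singles)
    poly <- polychoricMatrix(x[, bifItems, drop = FALSE])
    egaRes <- ega(poly, n = nrow(x))
    bstr <- specAssign[bifItems]
    bstr[bifItems %in% singles] <- NA  # single-item indicators: general only
    bfit <- fitBifactorGrm(x[, bifItems, drop = FALSE], bstr,
                           tol = config$grmTol,
                           maxCycles = config$grmMaxCycles)
    li <- limitedInformationFit(bfit, poly, nrow(x))
    bfit@fit <- li[c("srmr", "rmsea", "tli", "df")]
    idx <- bifactorIndices(bfit)
    verdict <- interpretabilityRules(idx)
    list(cfa = cfaScores, cfaUsed = cfaUsed, ega = egaRes, bifactor = bfit,
         indices = idx, verdict = verdict)
  })
  if (!is.null(structureRes)) {
    .writeJson(list(
      cfa = structureRes$cfa[c("chisq", "df", "cfi", "rmsea", "srmr",
                               "estimator")],
      cfaUsed = structureRes$cfaUsed,
      egaCommunities = as.list(setNames(structureRes$ega$communities,
                                        structureRes$ega$items)),
      fit = structureRes$bifactor@fit,
      omegaT = structureRes$indices@omegaT,
      omegaH = structureRes$indices@omegaH,
      ecvG = structureRes$indices@ecvG,
      subscales = as.data.frame(structureRes$indices@subscales),
      generalVerdict = structureRes$verdict$general,
      ruleTrace = structureRes$verdict$ruleTrace),
      file.path(config$outDir, "structure.json"))
    writeLines(formatIndexTable(structureRes$indices),
               file.path(config$outDir, "indices.md"))
  }
  ## stage 3: EAP scores for interpretable constructs only
  scores <- stage("scores", {
    stopifnot(!is.null(structureRes))
    v <- structureRes$verdict
    emit <- list()
    eapBif <- eapScores(structureRes$bifactor,
                        x[, structureRes$bifactor@items, drop = FALSE])
    if (v$general == "strong")
      emit[["general"]] <- eapBif[eapBif$factor == "general", ]
    if (nrow(v$subscales))
      for (i in which(v$subscales$addedValue)) {
        g <- v$subscales$subscale[i]
        fit <- refinement[[g]]$fit
        sc <- eapScores(fit, x[, fit@items, drop = FALSE])
        emit[[g]] <- sc
      }
    emit
  })
  if (!is.null(scores) && length(scores)) {
    scoreDf <- do.call(rbind, lapply(names(scores), function(nm)
      cbind(score = nm, scores[[nm]])))
    write.csv(scoreDf, file.path(config$outDir, "eap_scores.csv"),
              row.names = FALSE)
  }
  ## stage 4: correlate IDA
  idaRes <- stage("ida", if (is.null(config$correlates) || !length(scores)) NULL else {
    corr <- config$data$correlates
    summaries <- list()
    for (nm in names(scores)) {
      sc <- scores[[nm]]
      sc <- sc[match(corr$person_id, sc$person_id), ]
      for (i in seq_len(nrow(config$correlates))) {
        cn <- config$correlates$name[i]
        tp <- config$correlates$type[i]
        spec <- idaSpec(effectType = if (tp == "continuous") "r" else "d",
                        chains = config$idaChains, draws = config$idaDraws,
                        warmup = config$idaWarmup, seed = config$seed + i,
                        minCases = config$minCases)
        fit <- fitIdaModel(sc$theta, corr[[cn]], corr$study_id, spec,
                           outcome = nm, correlate = cn)
        summaries[[paste(nm, cn, sep = "~")]] <- effectSizeSummary(fit)
      }
    }
    summaries
  })
  if (!is.null(idaRes) && length(idaRes)) {
    writeIdaSummaries(idaRes, file.path(config$outDir, "ida_summaries.csv"))
    write.csv(evidenceTally(idaRes),
              file.path(config$outDir, "evidence_tally.csv"),
              row.names = FALSE)
  }
  if (length(errors))
    .writeJson(errors, file.path(config$outDir, "errors.json"))
  ## manifest
  arts <- sort(setdiff(list.files(config$outDir), "manifest.json"))
  manifest <- list(
    construct = config$constructName, seed = config$seed,
    package = as.character(utils::packageVersion("sensefactor")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    artifacts = as.list(setNames(
      unname(tools::md5sum(file.path(config$outDir, arts))), arts)))
  .writeJson(manifest, file.path(config$outDir, "manifest.json"))
  invisible(list(refinement = refinement, structure = structureRes,
                 scores = scores, ida = idaRes, errors = errors,
                 manifest = manifest, outDir = config$outDir))
}

#' Render a Markdown report from a pipeline run directory
#'
#' Assembles the refinement decisions, structure evaluation, bifactor index
#' table and (when present) the correlate effect-size table into a single
#' Markdown document. An empty directory produces an explicit "no results"
#' page rather than an error.
#'
#' @param runDir directory written by [runPipeline()].
#' @param path output path (default `report.md` inside `runDir`).
#' @return the output path, invisibly.
#' @export
renderReport <- function(runDir, path = file.path(runDir, "report.md")) {
  files <- list.files(runDir)
  lines <- c("# Sensory construct analysis report", "")
  if (!length(setdiff(files, "report.md"))) {
    writeLines(c(lines, "No results found in this run directory."), path)
    return(invisible(path))
  }
  if ("manifest.json" %in% files) {
    mf <- jsonlite::read_json(file.path(runDir, "manifest.json"))
    lines <- c(lines, sprintf("Construct: **%s** (seed %s, sensefactor %s)",
                              mf$construct, mf$seed, mf$package), "")
  }
  if ("refinement.json" %in% files) {
    rf <- jsonlite::read_json(file.path(runDir, "refinement.json"))
    lines <- c(lines, "## Scale refinement", "",
               "| Subconstruct | Decision | Items |", "| --- | --- | --- |")
    for (g in names(rf))
      lines <- c(lines, sprintf("| %s | %s | %s |", g, rf[[g]]$decision,
                                paste(unlist(rf[[g]]$items), collapse = ", ")))
    lines <- c(lines, "")
  }
  if ("structure.json" %in% files) {
    st <- jsonlite::read_json(file.path(runDir, "structure.json"))
    lines <- c(lines, "## Structure evaluation", "",
               sprintf("- CFA (%s, %s): CFI = %.3f, RMSEA = %.3f, SRMR = %.3f",
                       st$cfa$estimator, st$cfaUsed, st$cfa$cfi,
                       st$cfa$rmsea, st$cfa$srmr),
               sprintf("- EGA communities: %d",
                       length(unique(unlist(st$egaCommunities)))),
               sprintf("- omegaT = %.3f, omegaH = %.3f, ECV_G = %.3f",
                       st$omegaT, st$omegaH, st$ecvG),
               sprintf("- General factor verdict: **%s**", st$generalVerdict),
               "")
    if ("indices.md" %in% files)
      lines <- c(lines, "## Bifactor indices", "",
                 readLines(file.path(runDir, "indices.md")), "")
  }
  if ("ida_summaries.csv" %in% files) {
    ida <- read.csv(file.path(runDir, "ida_summaries.csv"))
    lines <- c(lines, "## Correlate associations", "",
               "| Outcome | Correlate | Effect | 95% HDI | log BF_ROPE | Category |",
               "| --- | --- | --- | --- | --- | --- |")
    for (i in seq_len(nrow(ida)))
      lines <- c(lines, with(ida[i, ], sprintf(
        "| %s | %s | %s = %.3f | [%.3f, %.3f] | %.2f | %s |", outcome,
        correlate, effect_type, median, hdi_lower, hdi_upper, log_bf_rope,
        category)))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
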