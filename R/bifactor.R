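# Confirmatory bifactor graded response model by MML-EM with dimension
# reduction: conditional on the general factor, each specific factor is
# integrated out independently over its own item group, so the E-step costs
# O(Q^2 * items) rather than O(Q^(1 + S)). Within each item group, persons
# are additionally collapsed to their distinct group-response patterns
# (including missingness), which keeps the Q^2 computations at
# pattern-level cost.

.validateStructure <- function(items, structure) {
  if (is.null(names(structure))) names(structure) <- items
  structure <- structure[items]
  spec <- unique(structure[!is.na(structure)])
  for (s in spec)
    if (sum(structure == s, na.rm = TRUE) < 2L)
      .stopf(paste0("specific factor '%s' has fewer than 2 items; ",
                    "declare single-item indicators as general-only (NA)"), s)
  structure
}

# Pattern bookkeeping per item group: distinct rows of x over the group's
# items (missingness included), person -> pattern index, and per-pattern
# responses.
.groupPatterns <- function(x, jj) {
  sub <- x[, jj, drop = FALSE]
  key <- do.call(paste, c(as.data.frame(sub), sep = "\r"))
  uk <- unique(key)
  idx <- match(key, uk)
  first <- match(uk, key)
  list(idx = idx, xPat = sub[first, , drop = FALSE], nPat = length(uk))
}

# Dimension-reduced likelihood pieces shared by the E-step and EAP scoring.
.bifactorPieces <- function(x, pars, structure, quad) {
  tg <- quad$nodes; w <- quad$weights; Q <- length(tg)
  n <- nrow(x)
  grid_g <- rep(tg, each = Q)    # qg blocks, qs fastest within a block
  grid_s <- rep(tg, times = Q)
  wS <- w[rep(seq_len(Q), times = Q)]
  Wagg <- kronecker(diag(Q), matrix(w, ncol = 1))  # Q^2 -> Q over qs
  spec <- unique(structure[!is.na(structure)])
  groups <- list()
  for (s in spec) {
    jj <- which(!is.na(structure) & structure == s)
    gp <- .groupPatterns(x, jj)
    logL <- matrix(0, gp$nPat, Q * Q)
    for (k in seq_along(jj)) {
      j <- jj[k]
      lp <- log(.catProbsFromEta(.itemEta(pars[[j]]$a, pars[[j]]$c, grid_g,
                                          pars[[j]]$aS, grid_s)))
      op <- which(!is.na(gp$xPat[, k]))
      logL[op, ] <- logL[op, ] + lp[gp$xPat[op, k], , drop = FALSE]
    }
    LsPat <- exp(logL)
    mPat <- LsPat %*% Wagg
    groups[[s]] <- list(jj = jj, gp = gp, LsPat = LsPat, mPat = mPat,
                        mPers = mPat[gp$idx, , drop = FALSE])
  }
  gOnly <- which(is.na(structure))
  logLg <- matrix(0, n, Q)
  for (j in gOnly) {
    lp <- log(.catProbsFromEta(.itemEta(pars[[j]]$a, pars[[j]]$c, tg)))
    oj <- which(!is.na(x[, j]))
    logLg[oj, ] <- logLg[oj, ] + lp[x[oj, j], , drop = FALSE]
  }
  A <- exp(sweep(logLg, 2L, log(w), "+"))
  for (s in spec) A <- A * groups[[s]]$mPers
  lik <- rowSums(A)
  list(A = A, lik = lik, groups = groups, grid_g = grid_g, grid_s = grid_s,
       wS = wS, spec = spec, gOnly = gOnly, Q = Q)
}

#' Fit a confirmatory bifactor graded response model
#'
#' Every item loads on the general factor; items assigned to a specific
#' factor additionally load there (simple structure: at most one specific
#' factor per item). Single-item subconstruct indicators must be declared
#' general-only (`NA` in `structure`); a specific factor with fewer than two
#' items is rejected. Estimation is MML-EM with the bifactor dimension
#' reduction, so the marginal likelihood is exact on the quadrature grid and
#' identical to brute-force multidimensional quadrature (see
#' [bruteForceLogLik()]).
#'
#' @inheritParams fitGrm
#' @param structure named character vector mapping each item to its specific
#'   factor (`NA` = general only).
#' @return a [GrmSolution-class].
#' @export
fitBifactorGrm <- function(x, structure, items = NULL, nCategories = 5L,
                           quad = quadratureGrid(), tol = 1e-5,
                           maxCycles = 500L) {
  x <- .coerceResponses(x, items)
  structure <- .validateStructure(colnames(x), structure)
  n <- nrow(x); p <- ncol(x)
  pars <- .startValues(x, nCategories)
  Q <- length(quad$nodes)
  catIndPers <- lapply(seq_len(p), function(j) {
    v <- x[!is.na(x[, j]), j]
    ind <- matrix(0, length(v), nCategories)
    ind[cbind(seq_along(v), v)] <- 1
    ind
  })
  emStep <- function(vec) {
    prs <- .unpackPars(vec, pars, structure)
    pc <- .bifactorPieces(x, prs, structure, quad)
    ll <- sum(log(pc$lik))
    postG <- pc$A / pc$lik
    for (j in pc$gOnly) {
      oj <- which(!is.na(x[, j]))
      r <- crossprod(catIndPers[[j]], postG[oj, , drop = FALSE])
      upd <- .mstepItem(r, quad$nodes, start = prs[[j]])
      prs[[j]]$a <- upd$a; prs[[j]]$c <- upd$c
    }
    for (s in pc$spec) {
      g <- pc$groups[[s]]
      B <- postG / pmax(g$mPers, 1e-300)
      B[g$mPers <= 0] <- 0
      Bagg <- rowsum(B, g$gp$idx)                       # nPat x Q
      Fs <- Bagg[, rep(seq_len(Q), each = Q), drop = FALSE] *
        g$LsPat * matrix(pc$wS, g$gp$nPat, Q^2, byrow = TRUE)
      for (k in seq_along(g$jj)) {
        j <- g$jj[k]
        op <- which(!is.na(g$gp$xPat[, k]))
        ind <- matrix(0, length(op), nCategories)
        ind[cbind(seq_along(op), g$gp$xPat[op, k])] <- 1
        r <- crossprod(ind, Fs[op, , drop = FALSE])
        upd <- .mstepItem(r, pc$grid_g, pc$grid_s, start = prs[[j]],
                          hasSpecific = TRUE)
        prs[[j]]$a <- upd$a; prs[[j]]$aS <- upd$aS; prs[[j]]$c <- upd$c
      }
    }
    list(pars = .packPars(prs, structure), ll = ll)
  }
  dr <- .emDriver(.packPars(pars, structure), emStep, tol, maxCycles)
  pars <- .unpackPars(dr$pars, pars, structure)
  llFinal <- sum(log(.bifactorPieces(x, pars, structure, quad)$lik))
  llHist <- c(dr$llHist, llFinal)
  converged <- dr$converged
  cyc <- dr$nSteps
  flags <- dr$flags
  aG <- vapply(pars, `[[`, numeric(1), "a")
  aS <- vapply(seq_len(p), function(j)
    if (is.na(structure[j])) 0 else pars[[j]]$aS, numeric(1))
  if (any(abs(c(aG, aS)) > 25)) flags <- c(flags, "Heywood-like slope (|a| > 25)")
  # sign identification: a specific factor is defined up to reflection
  for (s in unique(structure[!is.na(structure)])) {
    jj <- which(!is.na(structure) & structure == s)
    if (sum(aS[jj]) < 0) aS[jj] <- -aS[jj]
  }
  lam <- standardizeLoadings(aG, aS)
  sol <- new("GrmSolution", items = colnames(x), slopesG = aG, slopesS = aS,
             intercepts = lapply(pars, `[[`, "c"),
             structure = unname(structure), loadings = lam,
             logLik = llHist[length(llHist)], logLikHistory = llHist,
             nPersons = as.integer(n), fit = list(), rhoXX = numeric(0),
             omegaTotal = numeric(0), converged = converged, nCycles = cyc,
             flags = flags)
  eap <- eapScores(sol, x, quad)
  sol@rhoXX <- marginalReliability(sol, eap)
  sol@omegaTotal <- omegaCategorical(sol)
  sol
}

# EAP scores for a bifactor solution: the general factor integrates out the
# specific factors by the dimension-reduction identity; each specific factor
# integrates out the general factor.
.bifactorEap <- function(solution, x, quad) {
  p <- length(solution@items)
  pars <- lapply(seq_len(p), function(j)
    list(a = solution@slopesG[j], aS = solution@slopesS[j],
         c = solution@intercepts[[j]]))
  structure <- solution@structure
  pc <- .bifactorPieces(x, pars, structure, quad)
  tg <- quad$nodes; Q <- pc$Q
  n <- nrow(x)
  zero <- rowSums(!is.na(x)) == 0L
  postG <- pc$A / pmax(pc$lik, 1e-300)
  mG <- as.vector(postG %*% tg)
  vG <- as.vector(postG %*% tg^2) - mG^2
  mG[zero] <- 0; vG[zero] <- 1
  out <- data.frame(person_id = rownames(x), factor = "general", theta = mG,
                    sd = sqrt(pmax(vG, 0)), nObserved = rowSums(!is.na(x)))
  for (s in pc$spec) {
    g <- pc$groups[[s]]
    B <- postG / pmax(g$mPers, 1e-300)
    B[g$mPers <= 0] <- 0
    # posterior over the specific node, person-level:
    # postS[i, qs] = sum_qg B[i, qg] * w[qs] * LsPat[pat_i, (qg, qs)]
    postS <- matrix(0, n, Q)
    for (qg in seq_len(Q)) {
      block <- ((qg - 1L) * Q + 1L):(qg * Q)
      postS <- postS + B[, qg] * g$LsPat[g$gp$idx, block, drop = FALSE]
    }
    postS <- sweep(postS, 2L, quad$weights, "*")
    postS <- postS / pmax(rowSums(postS), 1e-300)
    mSc <- as.vector(postS %*% tg)
    vSc <- as.vector(postS %*% tg^2) - mSc^2
    noItem <- rowSums(!is.na(x[, g$jj, drop = FALSE])) == 0L
    mSc[noItem | zero] <- 0; vSc[noItem | zero] <- 1
    out <- rbind(out, data.frame(person_id = rownames(x), factor = s,
                                 theta = mSc, sd = sqrt(pmax(vSc, 0)),
                                 nObserved = rowSums(!is.na(x))))
  }
  out
}

#' Brute-force two-dimensional marginal log-likelihood
#'
#' Evaluates the bifactor marginal likelihood by direct quadrature over the
#' full (general x specific) grid without the dimension-reduction
#' factorization. Exists to verify the factorized likelihood on small
#' problems; cost grows as Q^(1 + S), so keep it to toy models with one
#' specific factor.
#'
#' @param solution a [GrmSolution-class] with a single specific factor.
#' @param x responses.
#' @param quad quadrature grid.
#' @return scalar log-likelihood.
#' @export
bruteForceLogLik <- function(solution, x, quad = quadratureGrid()) {
  if (is(x, "SensoryExperiment")) x <- t(responses(x))
  x <- as.matrix(x)[, solution@items, drop = FALSE]
  spec <- unique(solution@structure[!is.na(solution@structure)])
  stopifnot(length(spec) == 1L)
  tg <- quad$nodes; w <- quad$weights; Q <- length(tg)
  grid_g <- rep(tg, each = Q); grid_s <- rep(tg, times = Q)
  wJoint <- rep(w, each = Q) * rep(w, times = Q)
  n <- nrow(x)
  logL <- matrix(0, n, Q * Q)
  for (j in seq_along(solution@items)) {
    ts <- if (is.na(solution@structure[j])) NULL else grid_s
    lp <- log(.catProbsFromEta(.itemEta(solution@slopesG[j],
                                        solution@intercepts[[j]], grid_g,
                                        solution@slopesS[j], ts)))
    oj <- which(!is.na(x[, j]))
    logL[oj, ] <- logL[oj, ] + lp[x[oj, j], , drop = FALSE]
  }
  sum(.rowLogSumExp(sweep(logL, 2L, log(wJoint), "+")))
}
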