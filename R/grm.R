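# Graded response model estimation by Bock-Aitkin marginal maximum likelihood
# EM on a fixed quadrature grid. The unidimensional fitter lives here; the
# bifactor fitter (with dimension reduction over specific factors) is in
# bifactor.R and shares these internals.

# Category probabilities for one item at M latent points. eta is the matrix
# of boundary linear predictors ((K-1) x M); returns K x M probabilities.
.catProbsFromEta <- function(eta) {
  Pstar <- plogis(eta)
  K1 <- nrow(eta)
  p <- rbind(rep(1, ncol(eta)), Pstar) - rbind(Pstar, rep(0, ncol(eta)))
  pmax(p, 1e-300)
}

.itemEta <- function(aG, cvec, thetaG, aS = 0, thetaS = NULL) {
  lin <- aG * thetaG
  if (!is.null(thetaS)) lin <- lin + aS * thetaS
  outer(cvec, rep(1, length(lin))) + matrix(lin, length(cvec), length(lin),
                                            byrow = TRUE)
}

# unconstrained parameterization of decreasing intercepts
.packC <- function(cvec) {
  if (length(cvec) == 1L) return(cvec)
  c(cvec[1], log(-diff(cvec)))
}
.unpackC <- function(par) {
  if (length(par) == 1L) return(par)
  par[1] - cumsum(c(0, exp(par[-1])))
}

# Expected complete-data M-step for one item. r: K x M expected counts at the
# M grid points; tg/ts: latent coordinates of the grid points. Analytic
# gradient via the boundary derivative identity for cumulative-logit models.
.mstepItem <- function(r, tg, ts = NULL, start, hasSpecific = FALSE,
                       innerIter = 8L) {
  K1 <- length(start$c)
  nsk <- if (hasSpecific) 2L else 1L
  unpack <- function(par) {
    list(aG = par[1], aS = if (hasSpecific) par[2] else 0,
         cvec = .unpackC(par[-seq_len(nsk)]))
  }
  obj <- function(par) {
    u <- unpack(par)
    p <- .catProbsFromEta(.itemEta(u$aG, u$cvec, tg, u$aS, ts))
    -sum(r * log(p))
  }
  grad <- function(par) {
    u <- unpack(par)
    eta <- .itemEta(u$aG, u$cvec, tg, u$aS, ts)
    Pstar <- plogis(eta)                      # (K-1) x M
    q <- Pstar * (1 - Pstar)
    p <- .catProbsFromEta(eta)                # K x M
    rp <- r / p
    G <- q * (rp[-nrow(rp), , drop = FALSE] - rp[-1L, , drop = FALSE])
    dA <- sum(G %*% tg)
    dS <- if (hasSpecific) sum(G %*% ts) else NULL
    dC <- rowSums(G)                          # d(-ll)/d c_l
    # chain through c = c1 - cumsum(c(0, exp(d)))
    dpar <- c(dA, dS, sum(dC))
    if (K1 > 1L) {
      dtail <- vapply(seq_len(K1 - 1L), function(jj)
        -exp(par[nsk + 1L + jj]) * sum(dC[(jj + 1L):K1]), numeric(1))
      dpar <- c(dpar, dtail)
    }
    dpar
  }
  p0 <- c(start$a, if (hasSpecific) start$aS, .packC(start$c))
  fit <- nlminb(p0, obj, gradient = grad,
                control = list(iter.max = innerIter, trace = 0),
                lower = c(-30, if (hasSpecific) -30, rep(-Inf, K1)),
                upper = c(30, if (hasSpecific) 30, rep(Inf, K1)))
  u <- unpack(fit$par)
  list(a = u$aG, aS = u$aS, c = u$cvec)
}

# pack the full parameter set into one unconstrained vector (slopes plus
# log-gap intercepts), so that linear extrapolation preserves the intercept
# ordering
.packPars <- function(pars, structure) {
  unlist(lapply(seq_along(pars), function(j)
    c(pars[[j]]$a, if (!is.na(structure[j])) pars[[j]]$aS,
      .packC(pars[[j]]$c))))
}

.unpackPars <- function(vec, pars, structure) {
  pos <- 0L
  for (j in seq_along(pars)) {
    pars[[j]]$a <- vec[pos + 1L]; pos <- pos + 1L
    if (!is.na(structure[j])) { pars[[j]]$aS <- vec[pos + 1L]; pos <- pos + 1L }
    K1 <- length(pars[[j]]$c)
    pars[[j]]$c <- .unpackC(vec[pos + seq_len(K1)]); pos <- pos + K1
  }
  pars
}

# EM driver with SQUAREM-style safeguarded acceleration. `emStep` maps a
# packed parameter vector to list(pars = updated packed vector, ll =
# log-likelihood AT THE INPUT parameters). Accelerated jumps are only
# accepted when the subsequent E-step shows the log-likelihood did not
# decrease, so the recorded history stays monotone.
.emDriver <- function(p0, emStep, tol, maxCycles) {
  llHist <- numeric(0)
  nstep <- 0L; converged <- FALSE
  repeat {
    s1 <- emStep(p0); nstep <- nstep + 1L
    llHist <- c(llHist, s1$ll)
    d1 <- s1$pars - p0
    if (max(abs(d1)) < tol) { converged <- TRUE; p0 <- s1$pars; break }
    if (nstep >= maxCycles) { p0 <- s1$pars; break }
    s2 <- emStep(s1$pars); nstep <- nstep + 1L
    llHist <- c(llHist, s2$ll)
    d2 <- s2$pars - s1$pars
    if (max(abs(d2)) < tol) { converged <- TRUE; p0 <- s2$pars; break }
    if (nstep >= maxCycles) { p0 <- s2$pars; break }
    v <- d2 - d1
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) { p0 <- s2$pars; next }
    alpha <- min(max(-sqrt(sum(d1^2)) / nv, -64), -1)
    trial <- p0 - 2 * alpha * d1 + alpha^2 * v
    s3 <- emStep(trial); nstep <- nstep + 1L
    if (s3$ll >= llHist[length(llHist)] - 1e-8) {
      llHist <- c(llHist, s3$ll)
      p0 <- s3$pars
    } else {
      p0 <- s2$pars  # reject the jump, keep the plain EM state
    }
  }
  flags <- character(0)
  if (any(diff(llHist) < -1e-6))
    flags <- "log-likelihood decreased during EM"
  if (!converged)
    flags <- c(flags, sprintf("EM not converged in %d cycles", nstep))
  list(pars = p0, llHist = llHist, converged = converged, nSteps = nstep,
       flags = flags)
}

# starting intercepts from marginal category proportions
.startValues <- function(x, nCategories) {
  lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j][!is.na(x[, j])]
    counts <- tabulate(v, nbins = nCategories) + 0.5  # smoothed
    cum <- cumsum(counts) / sum(counts)
    cvec <- stats::qlogis(1 - cum[-nCategories])
    cvec <- cummin(cvec - 1e-3 * (seq_along(cvec) - 1))  # enforce decreasing
    list(a = 1.5, aS = 0.8, c = cvec)
  })
}

.coerceResponses <- function(x, items) {
  if (is(x, "SensoryExperiment")) x <- t(responses(x))
  x <- as.matrix(x)
  if (!is.null(items)) x <- x[, items, drop = FALSE]
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  keep <- rowSums(!is.na(x)) > 0L
  x[keep, , drop = FALSE]
}

#' Fit a unidimensional graded response model
#'
#' Bock-Aitkin marginal maximum likelihood: the E-step computes posterior
#' weights for each person on a fixed quadrature grid under a standard-normal
#' latent prior; the M-step updates each item's logistic slope and ordered
#' intercepts against the expected category counts. Missing item responses
#' are simply skipped in the person likelihood, so persons with any observed
#' item contribute. The marginal log-likelihood is non-decreasing across
#' cycles; convergence is declared when the largest absolute parameter change
#' falls below `tol`.
#'
#' @param x a [SensoryExperiment-class] or persons-by-items integer matrix.
#' @param items optional item subset.
#' @param nCategories response categories.
#' @param quad quadrature grid from [quadratureGrid()].
#' @param tol convergence tolerance on the maximum absolute parameter change.
#' @param maxCycles EM cycle cap; hitting it flags (not fails) the solution.
#' @return a [GrmSolution-class].
#' @export
fitGrm <- function(x, items = NULL, nCategories = 5L, quad = quadratureGrid(),
                   tol = 1e-5, maxCycles = 500L) {
  x <- .coerceResponses(x, items)
  n <- nrow(x); p <- ncol(x)
  tg <- quad$nodes; w <- quad$weights; Q <- length(tg)
  pars <- .startValues(x, nCategories)
  noSpec <- rep(NA_character_, p)
  logw <- log(w)
  obsList <- lapply(seq_len(p), function(j) which(!is.na(x[, j])))
  catInd <- lapply(seq_len(p), function(j) {
    v <- x[obsList[[j]], j]
    ind <- matrix(0, length(v), nCategories)
    ind[cbind(seq_along(v), v)] <- 1
    ind
  })
  eStep <- function(prs) {
    LQ <- matrix(0, n, Q)
    for (j in seq_len(p)) {
      logP <- log(.catProbsFromEta(.itemEta(prs[[j]]$a, prs[[j]]$c, tg)))
      oj <- obsList[[j]]
      LQ[oj, ] <- LQ[oj, ] + logP[x[oj, j], , drop = FALSE]
    }
    LQw <- sweep(LQ, 2L, logw, "+")
    lse <- .rowLogSumExp(LQw)
    list(ll = sum(lse), post = exp(LQw - lse))
  }
  emStep <- function(vec) {
    prs <- .unpackPars(vec, pars, noSpec)
    es <- eStep(prs)
    for (j in seq_len(p)) {
      r <- crossprod(catInd[[j]], es$post[obsList[[j]], , drop = FALSE])
      upd <- .mstepItem(r, tg, start = prs[[j]])
      prs[[j]]$a <- upd$a; prs[[j]]$c <- upd$c
    }
    list(pars = .packPars(prs, noSpec), ll = es$ll)
  }
  dr <- .emDriver(.packPars(pars, noSpec), emStep, tol, maxCycles)
  pars <- .unpackPars(dr$pars, pars, noSpec)
  llHist <- c(dr$llHist, eStep(pars)$ll)  # final ll at the final parameters
  converged <- dr$converged
  cyc <- dr$nSteps
  flags <- dr$flags
  a <- vapply(pars, `[[`, numeric(1), "a")
  if (any(abs(a) > 25)) flags <- c(flags, "Heywood-like slope (|a| > 25)")
  lam <- standardizeLoadings(a, rep(0, p))
  sol <- new("GrmSolution", items = colnames(x), slopesG = a,
             slopesS = rep(0, p), intercepts = lapply(pars, `[[`, "c"),
             structure = rep(NA_character_, p),
             loadings = lam, logLik = llHist[length(llHist)],
             logLikHistory = llHist, nPersons = as.integer(n), fit = list(),
             rhoXX = numeric(0), omegaTotal = numeric(0),
             converged = converged, nCycles = cyc, flags = flags)
  eap <- eapScores(sol, x)
  sol@rhoXX <- marginalReliability(sol, eap)
  sol@omegaTotal <- omegaCategorical(sol)
  sol
}

#' Convert logistic GRM slopes to standardized factor loadings
#'
#' Slopes are bridged to the probit metric by the 1.702 scaling constant,
#' then normalized: `lambda_d = a*_d / sqrt(1 + sum_d a*_d^2)`. The map is
#' invertible (see [loadingsToSlopes()]).
#'
#' @param aG,aS logistic slopes on the general and specific factor (vectors).
#' @return matrix with columns `lambdaG`, `lambdaS`.
#' @export
standardizeLoadings <- function(aG, aS = rep(0, length(aG))) {
  asg <- aG / .D_CONST
  ass <- aS / .D_CONST
  denom <- sqrt(1 + asg^2 + ass^2)
  cbind(lambdaG = asg / denom, lambdaS = ass / denom)
}

#' @rdname standardizeLoadings
#' @param lambdaG,lambdaS standardized loadings with
#'   `lambdaG^2 + lambdaS^2 < 1`.
#' @export
loadingsToSlopes <- function(lambdaG, lambdaS = rep(0, length(lambdaG))) {
  h2 <- lambdaG^2 + lambdaS^2
  stopifnot(all(h2 < 1))
  psi <- sqrt(1 - h2)
  cbind(aG = .D_CONST * lambdaG / psi, aS = .D_CONST * lambdaS / psi)
}

#' Expected a posteriori (EAP) latent-trait scores
#'
#' Posterior mean and SD of each latent factor per person under the
#' standard-normal prior, computed on the quadrature grid. For bifactor
#' solutions, the general-factor posterior integrates the specific factors
#' out by the same dimension-reduction identity used in estimation, and each
#' specific factor's posterior integrates out the general factor. Persons
#' with no observed items receive the prior (mean 0, SD 1) and are flagged.
#'
#' @param solution a converged [GrmSolution-class].
#' @param x responses (same orientation rules as [fitGrm()]); persons with
#'   zero observed items are retained.
#' @param quad quadrature grid.
#' @return data.frame with `person_id`, `factor`, `theta`, `sd`, `nObserved`.
#' @export
eapScores <- function(solution, x, quad = quadratureGrid()) {
  if (is(x, "SensoryExperiment")) x <- t(responses(x))
  x <- as.matrix(x)[, solution@items, drop = FALSE]
  if (is.null(rownames(x))) rownames(x) <- paste0("p", seq_len(nrow(x)))
  spec <- unique(solution@structure[!is.na(solution@structure)])
  if (length(spec) == 0L) {
    post <- .uniPosterior(solution, x, quad)
    zero <- rowSums(!is.na(x)) == 0L  # prior exactly, flagged via nObserved
    post$mean[zero] <- 0
    post$sd[zero] <- 1
    out <- data.frame(person_id = rownames(x), factor = "general",
                      theta = post$mean, sd = post$sd,
                      nObserved = rowSums(!is.na(x)))
  } else {
    out <- .bifactorEap(solution, x, quad)
  }
  rownames(out) <- NULL
  out
}

.uniPosterior <- function(solution, x, quad) {
  tg <- quad$nodes; w <- quad$weights; Q <- length(tg)
  n <- nrow(x)
  LQ <- matrix(0, n, Q)
  for (j in seq_along(solution@items)) {
    oj <- which(!is.na(x[, j]))
    if (!length(oj)) next
    logP <- log(.catProbsFromEta(.itemEta(solution@slopesG[j],
                                          solution@intercepts[[j]], tg)))
    LQ[oj, ] <- LQ[oj, ] + logP[x[oj, j], , drop = FALSE]
  }
  A <- exp(sweep(LQ, 2L, log(w), "+"))
  s <- rowSums(A)
  post <- A / s
  mean <- as.vector(post %*% tg)
  m2 <- as.vector(post %*% tg^2)
  list(mean = mean, sd = sqrt(pmax(m2 - mean^2, 0)))
}

#' Marginal reliability of EAP scores
#'
#' `rho_xx = 1 - mean(posterior SD^2)` under the unit-variance latent prior.
#'
#' @param solution a [GrmSolution-class] (used for the factor name).
#' @param eap output of [eapScores()].
#' @param factorName which factor to summarize (default the general factor).
#' @return scalar reliability.
#' @export
marginalReliability <- function(solution, eap, factorName = "general") {
  sds <- eap$sd[eap$factor == factorName]
  1 - mean(sds^2)
}

#' Model-based categorical total-score reliability (Green-Yang omega)
#'
#' Total-score reliability of the observed ordinal sum score implied by the
#' fitted loadings and thresholds, using bivariate-normal category
#' probabilities. The common-variance numerator uses the factor-implied
#' latent correlations (`lambda_j lambda_l`, including the diagonal), the
#' denominator the full model-implied latent correlations (unit diagonal).
#'
#' @param solution a [GrmSolution-class].
#' @return scalar omega.
#' @export
omegaCategorical <- function(solution) {
  lam <- solution@loadings
  p <- nrow(lam)
  # probit thresholds from logistic intercepts: tau = -c * psi / D
  psi <- sqrt(pmax(1 - rowSums(lam^2), 1e-8))
  tauList <- lapply(seq_len(p), function(j)
    sort(-solution@intercepts[[j]] * psi[j] / .D_CONST))
  # model-implied latent correlations
  Rfull <- tcrossprod(lam); diag(Rfull) <- 1
  Rcommon <- tcrossprod(lam[, "lambdaG"]) +
    tcrossprod(lam[, "lambdaS"]) * .sameSpecific(solution)
  num <- 0; den <- 0
  for (j in seq_len(p)) for (l in seq_len(p)) {
    tj <- tauList[[j]]; tl <- tauList[[l]]
    grid <- expand.grid(a = tj, b = tl)
    base <- tcrossprod(pnorm(tj), pnorm(tl))
    den <- den + sum(matrix(.pbvn(grid$a, grid$b, min(Rfull[j, l], 0.9999)),
                            length(tj)) - base)
    num <- num + sum(matrix(.pbvn(grid$a, grid$b,
                                  max(min(Rcommon[j, l], 0.9999), -0.9999)),
                            length(tj)) - base)
  }
  num / den
}

# indicator matrix: 1 when two items share a specific factor (incl. diagonal)
.sameSpecific <- function(solution) {
  s <- solution@structure
  outer(s, s, function(a, b) !is.na(a) & !is.na(b) & a == b) * 1
}

#' Total-score reliability from standardized loadings only
#'
#' The simple-formula omega used for reproducing published loading-table
#' coefficients: `omegaT = [(sum lambdaG)^2 + sum_s (sum lambdaS)^2] /
#' [same + sum(1 - h2)]`. See [bifactorIndices()] for the full index set.
#'
#' @param lambdaG,lambdaS standardized loadings.
#' @param structure specific-factor assignment (NA for general-only).
#' @return scalar omega.
#' @export
omegaFromLoadings <- function(lambdaG, lambdaS = rep(0, length(lambdaG)),
                              structure = rep(NA_character_, length(lambdaG))) {
  h2 <- lambdaG^2 + lambdaS^2
  sumS2 <- sum(vapply(unique(structure[!is.na(structure)]), function(s)
    sum(lambdaS[which(!is.na(structure) & structure == s)])^2, numeric(1)))
  num <- sum(lambdaG)^2 + sumS2
  num / (num + sum(1 - h2))
}

#' Limited-information fit of a GRM against a polychoric matrix
#'
#' SRMR is the root mean square of lower-triangle differences between the
#' sample polychoric correlations and the model-implied correlations
#' `Lambda Lambda' + diag(1 - h2)`. An approximate residual-based
#' quadratic-form statistic `T = n * sum(residual^2)` with
#' `df = p(p-1)/2 - #free loadings` feeds approximate RMSEA and TLI against
#' an independence null. With `df <= 0` (e.g. a just-identified 3-item
#' unidimensional model) only SRMR is reported and the others are `NA` with
#' a flag.
#'
#' @param solution a [GrmSolution-class].
#' @param poly a [PolychoricResult-class] (or plain correlation matrix) on
#'   the same items.
#' @param n sample size behind the polychoric matrix.
#' @return list with `srmr`, `rmsea`, `tli`, `df`, `stat`, `residuals`,
#'   `defined`.
#' @export
limitedInformationFit <- function(solution, poly, n) {
  S <- if (is(poly, "PolychoricResult")) polyCor(poly) else as.matrix(poly)
  S <- S[solution@items, solution@items]
  lam <- solution@loadings
  Sigma <- tcrossprod(lam[, "lambdaG"]) +
    tcrossprod(lam[, "lambdaS"]) * .sameSpecific(solution)
  diag(Sigma) <- 1
  Rres <- S - Sigma
  p <- ncol(S)
  lt <- lower.tri(S)
  srmr <- sqrt(mean(Rres[lt]^2))
  nfree <- sum(abs(lam[, "lambdaG"]) > 0) + sum(!is.na(solution@structure))
  df <- p * (p - 1) / 2 - nfree
  if (df <= 0) {
    return(list(srmr = srmr, rmsea = NA_real_, tli = NA_real_, df = df,
                stat = NA_real_, residuals = Rres, defined = FALSE))
  }
  stat <- n * sum(Rres[lt]^2)
  stat0 <- n * sum(S[lt]^2)
  df0 <- p * (p - 1) / 2
  rmsea <- sqrt(max(0, (stat - df) / (df * n)))
  tli <- ((stat0 / df0) - (stat / df)) / ((stat0 / df0) - 1)
  list(srmr = srmr, rmsea = rmsea, tli = tli, df = df, stat = stat,
       residuals = Rres, defined = TRUE)
}

#' Serialize a fitted GRM solution to JSON
#'
#' @param solution a [GrmSolution-class].
#' @param path output path.
#' @export
writeGrmSolution <- function(solution, path) {
  obj <- list(items = solution@items, slopesG = solution@slopesG,
              slopesS = solution@slopesS, intercepts = solution@intercepts,
              structure = solution@structure,
              loadings = as.data.frame(solution@loadings),
              logLik = solution@logLik, nPersons = solution@nPersons,
              fit = solution@fit, rhoXX = solution@rhoXX,
              omegaTotal = solution@omegaTotal,
              converged = solution@converged, flags = solution@flags)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
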