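# Bayesian random-effects integrative data analysis: a standardized sensory
# score regressed on one correlate with study-level random intercepts and
# slopes. The model is conditionally conjugate (normal slopes, half-t scales
# via the Huang-Wand inverse-gamma mixture), so the posterior is sampled
# with a blocked Gibbs sampler driven entirely by per-study sufficient
# statistics -- fast enough for simulation-based calibration at scale.

#' Specification of one integrative-data-analysis model
#'
#' @param effectType `"r"` for a continuous correlate (both variables
#'   standardized, the slope is the correlation) or `"d"` for a binary
#'   correlate (outcome standardized, 0/1 coding, the slope is Cohen's d).
#' @param rope region of practical equivalence for the effect size; defaults
#'   to \[-0.1, 0.1\] for r and \[-0.2, 0.2\] for d.
#' @param priorSdBeta SD of the normal prior on the standardized slope.
#' @param tauScale,sigmaScale,nu half-t prior scales (random-effect SDs and
#'   residual SD) and degrees of freedom.
#' @param chains,draws,warmup sampler settings; `draws` is the total
#'   post-warmup draw count across chains.
#' @param seed integer seed.
#' @param minCases minimum complete outcome-correlate pairs; below this the
#'   model is refused rather than fit.
#' @return list of class `IdaModelSpec`.
#' @export
idaSpec <- function(effectType = c("r", "d"), rope = NULL, priorSdBeta = 1,
                    tauScale = 0.5, sigmaScale = 1, nu = 3, chains = 4L,
                    draws = 2000L, warmup = 1000L, seed = 1L,
                    minCases = 100L) {
  effectType <- match.arg(effectType)
  if (is.null(rope)) rope <- if (effectType == "r") c(-0.1, 0.1) else c(-0.2, 0.2)
  structure(list(effectType = effectType, rope = rope,
                 priorSdBeta = priorSdBeta, tauScale = tauScale,
                 sigmaScale = sigmaScale, nu = nu, chains = as.integer(chains),
                 draws = as.integer(draws), warmup = as.integer(warmup),
                 seed = as.integer(seed), minCases = as.integer(minCases)),
            class = "IdaModelSpec")
}

.rinvgamma <- function(n, shape, rate) 1 / rgamma(n, shape = shape, rate = rate)

# split-Rhat over a draws-by-chains matrix
.splitRhat <- function(m) {
  half <- floor(nrow(m) / 2)
  sub <- cbind(m[seq_len(half), , drop = FALSE],
               m[half + seq_len(half), , drop = FALSE])
  mns <- colMeans(sub); vrs <- apply(sub, 2, var)
  W <- mean(vrs); B <- half * var(mns)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Fit the Bayesian random-effects IDA model
#'
#' `y_is = b0 + b1 x_is + u0s + u1s x_is + e_is`, with `u0s ~ N(0, tau0^2)`,
#' `u1s ~ N(0, tau1^2)` (independent), `e ~ N(0, sigma^2)`. The outcome is
#' standardized on the pooled observed sample; a continuous correlate is
#' standardized, a binary one coded 0/1. Pairs with fewer than
#' `spec$minCases` complete observations are refused with a reason.
#' Convergence requires split-Rhat below 1.01 on the slope.
#'
#' @param y numeric outcome (the sensory score).
#' @param x the correlate.
#' @param study study membership (factor/character).
#' @param spec an [idaSpec()].
#' @param outcome,correlate labels carried into summaries.
#' @return list of class `IdaDraws` (draws, per-study statistics, rhat), or
#'   a refused [IdaEffectSummary-class] when too few cases are available.
#' @export
fitIdaModel <- function(y, x, study, spec = idaSpec(), outcome = "outcome",
                        correlate = "correlate") {
  ok <- !is.na(y) & !is.na(x)
  if (sum(ok) < spec$minCases) {
    return(new("IdaEffectSummary", outcome = outcome, correlate = correlate,
               effectType = spec$effectType, median = NA_real_,
               hdi = c(NA_real_, NA_real_), pRope = NA_real_,
               logBfRope = NA_real_, category = "not fit",
               tau2 = NA_real_, tau = NA_real_, i2 = NA_real_,
               icc = NA_real_, predictionInterval = c(NA_real_, NA_real_),
               rhat = NA_real_, nCases = as.integer(sum(ok)),
               nDraws = 0L, refused = TRUE,
               reason = sprintf("fewer than %d observed cases (%d)",
                                spec$minCases, sum(ok))))
  }
  y <- y[ok]; x <- x[ok]; study <- as.character(study[ok])
  y <- (y - mean(y)) / sd(y)
  if (spec$effectType == "r") x <- (x - mean(x)) / sd(x)
  sid <- unique(study)
  S <- length(sid)
  si <- match(study, sid)
  N <- length(y)
  ns <- tabulate(si, S)
  Sx <- rowsum(x, si)[, 1]; Sxx <- rowsum(x^2, si)[, 1]
  Sy <- rowsum(y, si)[, 1]; Sxy <- rowsum(x * y, si)[, 1]
  Syy <- rowsum(y^2, si)[, 1]
  nu <- spec$nu
  perChain <- ceiling(spec$draws / spec$chains)
  keepTot <- perChain * spec$chains
  drawsB1 <- matrix(NA_real_, perChain, spec$chains)
  store <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed * 1000L + ch)
    beta <- c(0, 0); u0 <- rep(0, S); u1 <- rep(0, S)
    sigma2 <- 1; tau02 <- 0.1; tau12 <- 0.1
    aSig <- 1; aT0 <- 1; aT1 <- 1
    keep <- matrix(NA_real_, perChain, 5,
                   dimnames = list(NULL, c("beta0", "beta1", "tau0sq",
                                           "tau1sq", "sigma2")))
    nIter <- spec$warmup + perChain
    for (it in seq_len(nIter)) {
      # collapsed fixed-effects update: random effects integrated out via
      # Woodbury on the per-study 2x2 sufficient statistics, so beta mixes
      # independently of the u's
      Aa <- ns / sigma2; Ab <- Sx / sigma2; Ad <- Sxx / sigma2
      Ga <- Aa + 1 / tau02; Gb <- Ab; Gd <- Ad + 1 / tau12
      detG <- Ga * Gd - Gb^2
      r1 <- Sy / sigma2; r2 <- Sxy / sigma2
      GiA11 <- (Gd * Aa - Gb * Ab) / detG; GiA12 <- (Gd * Ab - Gb * Ad) / detG
      GiA21 <- (-Gb * Aa + Ga * Ab) / detG; GiA22 <- (-Gb * Ab + Ga * Ad) / detG
      P11 <- Aa - (Aa * GiA11 + Ab * GiA21)
      P12 <- Ab - (Aa * GiA12 + Ab * GiA22)
      P22 <- Ad - (Ab * GiA12 + Ad * GiA22)
      Gir1 <- (Gd * r1 - Gb * r2) / detG; Gir2 <- (-Gb * r1 + Ga * r2) / detG
      q1 <- r1 - (Aa * Gir1 + Ab * Gir2)
      q2 <- r2 - (Ab * Gir1 + Ad * Gir2)
      qa <- sum(P11) + 1 / spec$priorSdBeta^2
      qb <- sum(P12)
      qd <- sum(P22) + 1 / spec$priorSdBeta^2
      detq <- qa * qd - qb^2
      c1 <- sum(q1); c2 <- sum(q2)
      mb <- c((qd * c1 - qb * c2) / detq, (-qb * c1 + qa * c2) / detq)
      w00 <- qd / detq; w01 <- -qb / detq; w11 <- qa / detq
      M11 <- sqrt(w00); M21 <- w01 / M11; M22 <- sqrt(pmax(w11 - M21^2, 1e-12))
      zb <- rnorm(2)
      beta <- mb + c(M11 * zb[1], M21 * zb[1] + M22 * zb[2])
      # random effects per study given beta (2x2 closed-form normal)
      pa <- ns / sigma2 + 1 / tau02
      pb <- Sx / sigma2
      pd <- Sxx / sigma2 + 1 / tau12
      b1v <- (Sy - beta[1] * ns - beta[2] * Sx) / sigma2
      b2v <- (Sxy - beta[1] * Sx - beta[2] * Sxx) / sigma2
      det <- pa * pd - pb^2
      m0 <- (pd * b1v - pb * b2v) / det
      m1 <- (-pb * b1v + pa * b2v) / det
      v00 <- pd / det; v01 <- -pb / det; v11 <- pa / det
      L11 <- sqrt(v00); L21 <- v01 / L11; L22 <- sqrt(pmax(v11 - L21^2, 1e-12))
      z1 <- rnorm(S); z2 <- rnorm(S)
      u0 <- m0 + L11 * z1
      u1 <- m1 + L21 * z1 + L22 * z2
      # residual variance (half-t via inverse-gamma mixture)
      a0 <- beta[1] + u0; a1 <- beta[2] + u1
      sse <- sum(Syy - 2 * a0 * Sy - 2 * a1 * Sxy + 2 * a0 * a1 * Sx +
                   a0^2 * ns + a1^2 * Sxx)
      sigma2 <- .rinvgamma(1, (nu + N) / 2, nu / aSig + max(sse, 1e-10) / 2)
      aSig <- .rinvgamma(1, (nu + 1) / 2, nu / sigma2 + 1 / spec$sigmaScale^2)
      tau02 <- .rinvgamma(1, (nu + S) / 2, nu / aT0 + sum(u0^2) / 2)
      aT0 <- .rinvgamma(1, (nu + 1) / 2, nu / tau02 + 1 / spec$tauScale^2)
      tau12 <- .rinvgamma(1, (nu + S) / 2, nu / aT1 + sum(u1^2) / 2)
      aT1 <- .rinvgamma(1, (nu + 1) / 2, nu / tau12 + 1 / spec$tauScale^2)
      if (it > spec$warmup)
        keep[it - spec$warmup, ] <- c(beta, tau02, tau12, sigma2)
    }
    store[[ch]] <- keep
    drawsB1[, ch] <- keep[, "beta1"]
  }
  draws <- do.call(rbind, store)
  rhat <- .splitRhat(drawsB1)
  SSxc <- pmax(Sxx - Sx^2 / ns, 1e-8)
  structure(list(draws = as.data.frame(draws), rhat = rhat,
                 nCases = N, nStudies = S, varX = var(x), SSxc = SSxc,
                 spec = spec, outcome = outcome, correlate = correlate),
            class = "IdaDraws")
}

#' ROPE Bayes factor and evidence category from posterior draws
#'
#' `BF_ROPE` compares the posterior odds of the effect lying outside versus
#' inside the region of practical equivalence to the same prior odds
#' (computed analytically from the normal effect prior), so positive
#' `log(BF_ROPE)` is evidence for a practically meaningful effect. Posterior
#' proportions are clipped to `[1/(4 n), 1 - 1/(4 n)]` to avoid infinities.
#' Categories follow the log(3)/log(10) ladders: above 2.3 strong effect,
#' 1.1-2.3 moderate effect, within (-1.1, 1.1) inconclusive, below -1.1 /
#' -2.3 moderate / strong null.
#'
#' @param draws posterior draws of the effect size (at least 2000
#'   recommended).
#' @param rope length-2 interval.
#' @param priorSd SD of the (mean-zero normal) prior on the effect.
#' @return list with `pRope`, `logBf`, `category`.
#' @export
ropeBayesFactor <- function(draws, rope, priorSd = 1) {
  n <- length(draws)
  postIn <- mean(draws >= rope[1] & draws <= rope[2])
  eps <- 1 / (4 * n)
  postIn <- min(max(postIn, eps), 1 - eps)
  priorIn <- pnorm(rope[2] / priorSd) - pnorm(rope[1] / priorSd)
  logBf <- log((1 - postIn) / postIn) - log((1 - priorIn) / priorIn)
  list(pRope = mean(draws >= rope[1] & draws <= rope[2]), logBf = logBf,
       category = .categoryFromLogBf(logBf))
}

# five-way evidence ladder with boundaries at log(3) and log(10)
.categoryFromLogBf <- function(logBf) {
  thMod <- log(3); thStr <- log(10)
  if (logBf > thStr) "strong effect"
  else if (logBf > thMod) "moderate effect"
  else if (logBf < -thStr) "strong null"
  else if (logBf < -thMod) "moderate null"
  else "inconclusive"
}

#' Summarize an IDA posterior into an effect-size report
#'
#' Posterior median and 95% highest-density interval of the effect size
#' (the standardized slope: r for continuous, d for binary correlates),
#' `P_ROPE` and `log(BF_ROPE)` with the five-way evidence category,
#' heterogeneity indices, and the 95% prediction interval for a new study
#' (`b1 + u1_new`, `u1_new ~ N(0, tau1^2)` per draw). Summaries are refused
#' when the sampler has not converged (split-Rhat >= 1.01).
#'
#' @param fit an `IdaDraws` from [fitIdaModel()] (a refused
#'   [IdaEffectSummary-class] passes through unchanged).
#' @return an [IdaEffectSummary-class].
#' @export
effectSizeSummary <- function(fit) {
  if (is(fit, "IdaEffectSummary")) return(fit)
  stopifnot(inherits(fit, "IdaDraws"))
  spec <- fit$spec
  if (fit$rhat >= 1.01) {
    return(new("IdaEffectSummary", outcome = fit$outcome,
               correlate = fit$correlate, effectType = spec$effectType,
               median = NA_real_, hdi = c(NA_real_, NA_real_),
               pRope = NA_real_, logBfRope = NA_real_,
               category = "not converged", tau2 = NA_real_, tau = NA_real_,
               i2 = NA_real_, icc = NA_real_,
               predictionInterval = c(NA_real_, NA_real_), rhat = fit$rhat,
               nCases = as.integer(fit$nCases),
               nDraws = nrow(fit$draws), refused = TRUE,
               reason = sprintf("split-Rhat %.3f >= 1.01", fit$rhat)))
  }
  b1 <- fit$draws$beta1
  hdi <- .hdiFromDraws(b1, 0.95)
  bf <- ropeBayesFactor(b1, spec$rope, spec$priorSdBeta)
  het <- heterogeneitySummary(fit)
  new("IdaEffectSummary", outcome = fit$outcome, correlate = fit$correlate,
      effectType = spec$effectType, median = median(b1),
      hdi = unname(hdi), pRope = bf$pRope, logBfRope = bf$logBf,
      category = bf$category, tau2 = het$tau2, tau = het$tau, i2 = het$i2,
      icc = het$icc, predictionInterval = het$predictionInterval,
      rhat = fit$rhat, nCases = as.integer(fit$nCases),
      nDraws = length(b1), refused = FALSE, reason = "")
}

#' Heterogeneity summaries from an IDA posterior
#'
#' `tau^2` is the posterior median of the random-slope variance (its square
#' root `tau` is also reported); `I^2 = tau1^2 / (tau1^2 + vbar)` with
#' `vbar` the mean study-level sampling variance of the slope
#' (`sigma^2 / SSx_s`); `ICC = (tau0^2 + tau1^2 Var(x)) / (tau0^2 + tau1^2
#' Var(x) + sigma^2)`; the 95% prediction interval adds a fresh study-level
#' slope deviation to each posterior draw.
#'
#' @param fit an `IdaDraws` object.
#' @return list with `tau2`, `tau`, `i2`, `icc`, `predictionInterval`.
#' @export
heterogeneitySummary <- function(fit) {
  stopifnot(inherits(fit, "IdaDraws"))
  d <- fit$draws
  vbar <- outer(d$sigma2, 1 / fit$SSxc) |> rowMeans()
  i2 <- d$tau1sq / (d$tau1sq + vbar)
  icc <- (d$tau0sq + d$tau1sq * fit$varX) /
    (d$tau0sq + d$tau1sq * fit$varX + d$sigma2)
  set.seed(fit$spec$seed * 1000L + 999L)
  pred <- d$beta1 + rnorm(nrow(d), 0, sqrt(d$tau1sq))
  list(tau2 = median(d$tau1sq), tau = median(sqrt(d$tau1sq)),
       i2 = median(i2), icc = median(icc),
       predictionInterval = unname(quantile(pred, c(0.025, 0.975))))
}

#' Tally evidence categories across a battery of IDA summaries
#'
#' @param summaries list of [IdaEffectSummary-class] objects.
#' @return data.frame with counts and percentages per evidence category
#'   (refused models are tallied separately as `not fit`).
#' @export
evidenceTally <- function(summaries) {
  cats <- c("strong effect", "moderate effect", "inconclusive",
            "moderate null", "strong null", "not fit", "not converged")
  got <- vapply(summaries, function(s) s@category, character(1))
  counts <- vapply(cats, function(cc) sum(got == cc), integer(1))
  fitted <- sum(counts[1:5])
  data.frame(category = cats, count = counts,
             percent = ifelse(cats %in% cats[1:5] & fitted > 0,
                              100 * counts / max(fitted, 1), NA_real_),
             row.names = NULL)
}

#' Export IDA summaries to a tidy CSV
#'
#' One row per outcome-correlate pair with the posterior effect size, HDI,
#' ROPE statistics, heterogeneity indices and prediction interval.
#'
#' @param summaries list of [IdaEffectSummary-class] objects.
#' @param path CSV path.
#' @export
writeIdaSummaries <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s) data.frame(
    outcome = s@outcome, correlate = s@correlate, effect_type = s@effectType,
    n = s@nCases, median = s@median, hdi_lower = s@hdi[1],
    hdi_upper = s@hdi[2], p_rope = s@pRope, log_bf_rope = s@logBfRope,
    category = s@category, tau2 = s@tau2, tau = s@tau, i2 = s@i2,
    icc = s@icc, pi_lower = s@predictionInterval[1],
    pi_upper = s@predictionInterval[2], rhat = s@rhat,
    refused = s@refused, reason = s@reason)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
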