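test_that("the hierarchical model recovers a planted correlation", {
  d <- idaSimData(0.3, 0.05, seed = 5)
  fit <- fitIdaModel(d$y, d$x, d$study, idaSpec(seed = 2))
  s <- effectSizeSummary(fit)
  expect_false(s@refused)
  expect_lt(fit$rhat, 1.01)
  expect_lt(abs(s@median - 0.3), 0.08)
  expect_true(s@hdi[1] <= s@median && s@median <= s@hdi[2])
  expect_identical(s@category, "strong effect")
})

test_that("a permuted (null) correlate lands near zero with high P_ROPE", {
  d <- idaSimData(0.25, 0.05, seed = 6)
  set.seed(99)
  xPerm <- sample(d$x)
  s <- effectSizeSummary(fitIdaModel(d$y, xPerm, d$study, idaSpec(seed = 3)))
  expect_lt(abs(s@median), 0.05)
  expect_gt(s@pRope, 0.9)
})

test_that("fewer than 100 cases yields a refusal object, not an estimate", {
  s <- fitIdaModel(rnorm(80), rnorm(80), rep(1:4, 20), idaSpec(seed = 1))
  expect_s4_class(s, "IdaEffectSummary")
  expect_true(s@refused)
  expect_match(s@reason, "fewer than 100")
  expect_identical(s@category, "not fit")
  # exactly at the floor the model is fit
  d <- idaSimData(0, 0, S = 5, n = 20, seed = 7)
  fit <- fitIdaModel(d$y, d$x, d$study, idaSpec(seed = 4))
  expect_false(is(fit, "IdaEffectSummary"))
})

test_that("HDI matches an exhaustive shortest-interval search", {
  set.seed(41)
  draws <- c(rnorm(1500), rnorm(500, 3))   # bimodal-ish, skewed
  got <- sensefactor:::.hdiFromDraws(draws, 0.90)
  # independent oracle: enumerate every pair of order statistics covering
  # at least 90% of draws and take the narrowest
  x <- sort(draws)
  n <- length(x)
  need <- ceiling(0.90 * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - need + 1)) {
    j <- i + need - 1
    if (x[j] - x[i] < best[2] - best[1]) best <- c(x[i], x[j])
  }
  expect_equal(unname(got), best, tolerance = 1e-8)
  # symmetric unimodal draws: HDI close to the equal-tailed interval
  set.seed(42)
  sym <- rnorm(20000)
  hdi <- sensefactor:::.hdiFromDraws(sym, 0.95)
  expect_equal(unname(hdi), unname(quantile(sym, c(0.025, 0.975))),
               tolerance = 0.08)
})

test_that("ROPE Bayes factor boundaries and degenerate posteriors behave", {
  # posterior identical to the prior: log BF ~ 0, inconclusive
  set.seed(43)
  b <- ropeBayesFactor(rnorm(8000), c(-0.1, 0.1), priorSd = 1)
  expect_lt(abs(b$logBf), 0.3)
  expect_identical(b$category, "inconclusive")
  # point mass far outside the ROPE: strong effect, P_ROPE 0
  b2 <- ropeBayesFactor(rep(0.5, 4000), c(-0.1, 0.1))
  expect_identical(b2$category, "strong effect")
  expect_equal(b2$pRope, 0)
  # draws entirely inside the ROPE: P_ROPE = 1, strong null
  b3 <- ropeBayesFactor(runif(4000, -0.05, 0.05), c(-0.1, 0.1))
  expect_equal(b3$pRope, 1)
  expect_identical(b3$category, "strong null")
  # category boundaries sit exactly at log(3) and log(10)
  expect_identical(sensefactor:::.categoryFromLogBf(1.0987), "moderate effect")
  expect_identical(sensefactor:::.categoryFromLogBf(1.0985), "inconclusive")
  expect_identical(sensefactor:::.categoryFromLogBf(2.3027), "strong effect")
  expect_identical(sensefactor:::.categoryFromLogBf(-1.0987), "moderate null")
  expect_identical(sensefactor:::.categoryFromLogBf(-2.3027), "strong null")
})

test_that("heterogeneity summaries respond to the generating tau", {
  dHom <- idaSimData(0.2, 0, seed = 8)
  sHom <- effectSizeSummary(fitIdaModel(dHom$y, dHom$x, dHom$study,
                                        idaSpec(seed = 5)))
  dHet <- idaSimData(0.2, 0.2, S = 12, seed = 9)
  sHet <- effectSizeSummary(fitIdaModel(dHet$y, dHet$x, dHet$study,
                                        idaSpec(seed = 6)))
  # homogeneous: small I2, prediction interval close to the HDI (the
  # posterior tau is never exactly zero, so "close" means within a factor
  # of two, and much closer than under real heterogeneity)
  expect_lt(sHom@i2, 0.35)
  ratioHom <- diff(sHom@predictionInterval) / diff(sHom@hdi)
  ratioHet <- diff(sHet@predictionInterval) / diff(sHet@hdi)
  expect_lt(ratioHom, 2)
  expect_gt(ratioHet, ratioHom)
  # heterogeneous: prediction interval strictly wider than the HDI
  expect_gt(diff(sHet@predictionInterval), diff(sHet@hdi))
  expect_gt(sHet@tau, sHom@tau)
  # tau rank recovery across a grid, averaged over replicates
  taus <- c(0, 0.05, 0.15)
  est <- vapply(seq_along(taus), function(i) {
    mean(vapply(1:20, function(rep) {
      dd <- idaSimData(0.2, taus[i], S = 10, n = 200,
                       seed = 1000 * i + rep)
      effectSizeSummary(fitIdaModel(
        dd$y, dd$x, dd$study,
        idaSpec(seed = 500 + 20 * i + rep, draws = 1000,
                warmup = 500)))@tau
    }, numeric(1)))
  }, numeric(1))
  expect_identical(order(est), 1:3)
})

test_that("posterior matches the rjags oracle on one dataset", {
  skip_if_not_installed("rjags")
  d <- idaSimData(0.25, 0.1, S = 8, n = 120, seed = 77)
  fit <- fitIdaModel(d$y, d$x, d$study,
                     idaSpec(seed = 4, draws = 8000, warmup = 1000))
  ys <- (d$y - mean(d$y)) / sd(d$y)
  xs <- (d$x - mean(d$x)) / sd(d$x)
  model <- "model{
    for (i in 1:N){ y[i] ~ dnorm(b0 + u0[st[i]] + (b1+u1[st[i]])*x[i], 1/sig2) }
    for (s in 1:S){ u0[s] ~ dnorm(0, 1/t02); u1[s] ~ dnorm(0, 1/t12) }
    b0 ~ dnorm(0,1); b1 ~ dnorm(0,1)
    t0 ~ dt(0, 1/0.25, 3) T(0,); t1 ~ dt(0, 1/0.25, 3) T(0,)
    sg ~ dt(0, 1, 3) T(0,)
    t02 <- t0^2; t12 <- t1^2; sig2 <- sg^2
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = ys, x = xs, st = d$study,
                                      N = length(ys), S = 8),
                          n.chains = 2, quiet = TRUE)
  update(jm, 1500, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("b1"), 6000, progress.bar = "none")
  ref <- as.matrix(sm)[, "b1"]
  expect_lt(abs(median(fit$draws$beta1) - median(ref)), 0.02)
  expect_lt(abs(sd(fit$draws$beta1) - sd(ref)), 0.01)
})

test_that("evidence tallies count categories and percentages", {
  mk <- function(cat) new("IdaEffectSummary", outcome = "o", correlate = "c",
                          effectType = "r", median = 0, hdi = c(-0.1, 0.1),
                          pRope = 0.5, logBfRope = 0, category = cat,
                          tau2 = 0, tau = 0, i2 = 0, icc = 0,
                          predictionInterval = c(-0.1, 0.1), rhat = 1,
                          nCases = 100L, nDraws = 10L, refused = FALSE,
                          reason = "")
  tl <- evidenceTally(list(mk("strong effect"), mk("strong effect"),
                           mk("inconclusive"), mk("strong null")))
  expect_equal(sum(tl$count), 4)
  expect_equal(tl$count[tl$category == "strong effect"], 2L)
  expect_equal(tl$percent[tl$category == "strong effect"], 50)
  t1 <- evidenceTally(list(mk("moderate null")))
  expect_equal(sum(t1$count), 1)
})
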