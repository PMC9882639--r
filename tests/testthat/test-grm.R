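test_that("loading standardization follows the 1.702 bridge and inverts", {
  # a = 0 -> lambda = 0; a* = 1 -> lambda = 1/sqrt(2)
  expect_equal(unname(standardizeLoadings(0)[1, "lambdaG"]), 0)
  expect_equal(unname(standardizeLoadings(1.702)[1, "lambdaG"]), 1 / sqrt(2),
               tolerance = 1e-12)
  # round trip through the published first-row loading pair
  lam <- c(0.513, 0.699)
  sl <- loadingsToSlopes(lam[1], lam[2])
  back <- standardizeLoadings(sl[1, "aG"], sl[1, "aS"])
  expect_equal(unname(back[1, ]), lam, tolerance = 1e-12)
})

test_that("unidimensional GRM recovers generating slopes and is deterministic", {
  L <- list(items = paste0("i", 1:6), lambdaG = rep(0.66, 6),
            lambdaS = rep(0, 6), structure = rep(NA_character_, 6))
  d <- simulateSensoryData(syntheticSpec(nStudies = 1, nPerStudy = 2000,
                                         loadings = L, studySd = 0), seed = 7)
  fit <- fitGrm(d$se, tol = 1e-4)
  expect_true(fit@converged)
  # log-likelihood non-decreasing across EM history
  expect_true(all(diff(fit@logLikHistory) > -1e-6))
  # recovery within simulation error (~3 SE of a loading at n = 2000)
  expect_true(all(abs(fit@loadings[, "lambdaG"] - 0.66) < 0.06))
  # determinism: same data, same fit
  fit2 <- fitGrm(d$se, tol = 1e-4)
  expect_identical(fit@loadings, fit2@loadings)
})

test_that("a null-loading item is estimated near zero without disturbing others", {
  L <- list(items = paste0("i", 1:5), lambdaG = c(rep(0.66, 4), 0),
            lambdaS = rep(0, 5), structure = rep(NA_character_, 5))
  d <- simulateSensoryData(syntheticSpec(nStudies = 1, nPerStudy = 1500,
                                         loadings = L, studySd = 0), seed = 8)
  fit <- fitGrm(d$se, tol = 1e-4)
  expect_lt(abs(fit@loadings[5, "lambdaG"]), 0.08)
  expect_true(all(abs(fit@loadings[1:4, "lambdaG"] - 0.66) < 0.07))
})

test_that("EAP scores follow the prior for empty records and order monotonically", {
  L <- list(items = paste0("i", 1:4), lambdaG = rep(0.7, 4),
            lambdaS = rep(0, 4), structure = rep(NA_character_, 4))
  d <- simulateSensoryData(syntheticSpec(nStudies = 1, nPerStudy = 400,
                                         loadings = L, studySd = 0), seed = 9)
  fit <- fitGrm(d$se, tol = 1e-4)
  # all-missing person: prior mean 0, prior SD 1
  x <- rbind(matrix(NA_integer_, 1, 4,
                    dimnames = list("ghost", fit@items)))
  eap0 <- eapScores(fit, x)
  expect_equal(eap0$theta, 0)
  expect_equal(eap0$sd, 1)
  # raising one response raises the posterior mean
  xa <- matrix(c(3L, 3L, 3L, 2L), 1, dimnames = list("a", fit@items))
  xb <- matrix(c(3L, 3L, 3L, 4L), 1, dimnames = list("b", fit@items))
  expect_gt(eapScores(fit, xb)$theta, eapScores(fit, xa)$theta)
})

test_that("marginal reliability matches its EAP identity and the score-truth correlation", {
  L <- list(items = paste0("i", 1:6), lambdaG = rep(0.7, 6),
            lambdaS = rep(0, 6), structure = rep(NA_character_, 6))
  d <- simulateSensoryData(syntheticSpec(nStudies = 1, nPerStudy = 2000,
                                         loadings = L, studySd = 0), seed = 10)
  fit <- fitGrm(d$se, tol = 1e-4)
  eap <- eapScores(fit, d$se)
  rho <- marginalReliability(fit, eap)
  expect_equal(rho, 1 - mean(eap$sd^2))
  expect_gt(cor(eap$theta, d$truth$thetaG), sqrt(rho) - 0.05)
  # zero-slope scale carries no information
  sol0 <- fit
  sol0@slopesG <- rep(0, 6)
  sol0@loadings <- standardizeLoadings(rep(0, 6))
  eap0 <- eapScores(sol0, d$se)
  expect_lt(marginalReliability(sol0, eap0), 0.01)
  # very high slopes push reliability above 0.9 (quadrature identity)
  solHi <- fit
  solHi@slopesG <- rep(4 * 1.702, 6)
  solHi@loadings <- standardizeLoadings(solHi@slopesG)
  LHi <- list(items = paste0("i", 1:6),
              lambdaG = standardizeLoadings(rep(4 * 1.702, 6))[, 1],
              lambdaS = rep(0, 6), structure = rep(NA_character_, 6))
  dHi <- simulateSensoryData(syntheticSpec(nStudies = 1, nPerStudy = 500,
                                           loadings = LHi, studySd = 0),
                             seed = 11)
  fitHi <- fitGrm(dHi$se, tol = 1e-3, maxCycles = 100)
  eapHi <- eapScores(fitHi, dHi$se)
  expect_gt(marginalReliability(fitHi, eapHi), 0.9)
})

test_that("limited-information fit separates true and misspecified models", {
  # exact model-implied matrix gives SRMR 0
  lam <- c(0.6, 0.7, 0.5, 0.65)
  Sigma <- tcrossprod(lam); diag(Sigma) <- 1
  L <- list(items = paste0("i", 1:4), lambdaG = lam, lambdaS = rep(0, 4),
            structure = rep(NA_character_, 4))
  d <- simulateSensoryData(syntheticSpec(nStudies = 1, nPerStudy = 2000,
                                         loadings = L, studySd = 0), seed = 12)
  fit <- fitGrm(d$se, tol = 1e-4)
  dimnames(Sigma) <- list(fit@items, fit@items)
  solExact <- fit
  solExact@loadings <- cbind(lambdaG = lam, lambdaS = rep(0, 4))
  liExact <- limitedInformationFit(solExact, Sigma, 2000)
  expect_equal(liExact$srmr, 0, tolerance = 1e-12)
  # data simulated from the fitted model: SRMR inside the retention region
  poly <- polychoricMatrix(t(responses(d$se)))
  li <- limitedInformationFit(fit, poly, 2000)
  expect_lt(li$srmr, 0.05)
  # two-factor data forced into one factor fits worse than the true model
  L2 <- list(items = paste0("i", 1:4), lambdaG = c(0.3, 0.3, 0.3, 0.3),
             lambdaS = c(0.7, 0.7, 0.7, 0.7),
             structure = c("a", "a", "b", "b"))
  d2 <- simulateSensoryData(syntheticSpec(nStudies = 1, nPerStudy = 2000,
                                          loadings = L2, studySd = 0),
                            seed = 13)
  fit2 <- fitGrm(d2$se, tol = 1e-4)
  li2 <- limitedInformationFit(fit2, polychoricMatrix(t(responses(d2$se))),
                               2000)
  expect_gt(li2$srmr, li$srmr)
  # 3-item just-identified model: SRMR reported, RMSEA/TLI undefined
  fit3 <- fitGrm(t(responses(d$se))[, 1:3], tol = 1e-3, maxCycles = 100)
  li3 <- limitedInformationFit(fit3,
                               polychoricMatrix(t(responses(d$se))[, 1:3]),
                               2000)
  expect_false(li3$defined)
  expect_true(is.na(li3$tli) && is.na(li3$rmsea))
  expect_false(is.na(li3$srmr))
})

test_that("categorical omega and the loading-formula omega agree directionally", {
  L <- list(items = paste0("i", 1:5), lambdaG = rep(0.75, 5),
            lambdaS = rep(0, 5), structure = rep(NA_character_, 5))
  d <- simulateSensoryData(syntheticSpec(nStudies = 1, nPerStudy = 1500,
                                         loadings = L, studySd = 0), seed = 14)
  fit <- fitGrm(d$se, tol = 1e-4)
  omGY <- omegaCategorical(fit)
  omL <- omegaFromLoadings(fit@loadings[, "lambdaG"])
  expect_gt(omGY, 0.7)
  expect_gt(omL, 0.7)
  expect_lt(abs(omGY - omL), 0.1)
})
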