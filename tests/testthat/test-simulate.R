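test_that("generated category frequencies match the GRM-implied marginals", {
  L <- list(items = paste0("i", 1:3), lambdaG = c(0.5, 0.65, 0.8),
            lambdaS = rep(0, 3), structure = rep(NA_character_, 3))
  n <- 5000
  d <- simulateSensoryData(syntheticSpec(nStudies = 1, nPerStudy = n,
                                         loadings = L, studySd = 0),
                           seed = 15)
  x <- t(responses(d$se))
  tau <- seq(-2, 2, length.out = 4)
  sl <- loadingsToSlopes(L$lambdaG)
  psi <- sqrt(1 - L$lambdaG^2)
  quad <- quadratureGrid(201, c(-8, 8))
  for (j in 1:3) {
    cvec <- -1.702 * tau / psi[j]
    Pstar <- plogis(outer(cvec, sl[j, "aG"] * quad$nodes, "+"))
    pk <- rbind(1, Pstar) - rbind(Pstar, 0)
    marg <- as.vector(pk %*% quad$weights)  # implied marginal category probs
    obs <- tabulate(x[, j], 5) / n
    se3 <- 3 * sqrt(marg * (1 - marg) / n)
    expect_true(all(abs(obs - marg) < pmax(se3, 0.005)))
  }
})

test_that("the generator respects seeds, coverage patterns, and homogeneity", {
  spec <- syntheticSpec(nStudies = 4, nPerStudy = 50,
                        loadings = referenceLoadings("hypo"),
                        coverage = list(1:6, 7:11))
  d1 <- simulateSensoryData(spec, seed = 20)
  d2 <- simulateSensoryData(spec, seed = 20)
  expect_identical(responses(d1$se), responses(d2$se))
  # coverage: studies on pattern 2 have items 1:6 fully missing
  m <- responses(d1$se)
  s2 <- colData(d1$se)$study_id == "study2"
  expect_true(all(is.na(m[1:6, s2])))
  expect_true(all(!is.na(m[7:11, s2])))
  # infeasible target correlation refused
  expect_error(syntheticSpec(correlates = data.frame(
    name = "bad", type = "continuous", effect = 1.2, tau1 = 0)),
    "infeasible")
})

test_that("empirical polychorics track the model-implied matrix under the reference loadings", {
  L <- referenceLoadings("hypo")
  d <- simulateSensoryData(syntheticSpec(nStudies = 1, nPerStudy = 1500,
                                         loadings = L, studySd = 0),
                           seed = 16)
  pm <- polyCor(polychoricMatrix(t(responses(d$se))))
  same <- outer(L$structure, L$structure,
                function(a, b) !is.na(a) & !is.na(b) & a == b) * 1
  Sigma <- tcrossprod(L$lambdaG) + tcrossprod(L$lambdaS) * same
  diag(Sigma) <- 1
  lt <- lower.tri(Sigma)
  expect_lt(sqrt(mean((pm[lt] - Sigma[lt])^2)), 0.05)
})

test_that("homogeneous correlate effects replicate across resampled halves", {
  spec <- syntheticSpec(nStudies = 1, nPerStudy = 2000,
                        loadings = referenceLoadings("hypo"), studySd = 0,
                        correlates = data.frame(name = "cx",
                                                type = "continuous",
                                                effect = 0.4, tau1 = 0))
  d <- simulateSensoryData(spec, seed = 17)
  th <- d$truth$thetaG
  cx <- d$correlates$cx
  half <- seq_len(1000)
  r1 <- cor(th[half], cx[half])
  r2 <- cor(th[-half], cx[-half])
  expect_lt(abs(r1 - r2), 4 * sqrt(2 / 1000))
  expect_lt(abs(cor(th, cx) - 0.4), 0.06)
})

test_that("the fixture suite is deterministic and complete", {
  f1 <- makeFixtureSuite(1)
  f2 <- makeFixtureSuite(1)
  expect_identical(responses(f1$nullEffect$se), responses(f2$nullEffect$se))
  expect_identical(f1$plantedClusters, f2$plantedClusters)
  # the 23-item hyperreactivity loading fixture matches the packaged table
  expect_equal(length(f1$loadings$hyper$lambdaG), 23)
  expect_equal(f1$loadings$hyper$lambdaG[1], 0.513)
  expect_equal(f1$loadings$hyper$lambdaS[1], 0.699)
  # planted partition is recorded as ground truth
  expect_identical(f1$plantedClusters$partition, list(1:2, 3:4, 5:6))
  expect_s4_class(f1$toyBank, "ItemBank")
})
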