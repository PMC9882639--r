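test_that("published loading tables reproduce every printed ECV/h2/I-ECV cell", {
  hyper <- bifactorIndices(referenceLoadings("hyper"))
  hypo <- bifactorIndices(referenceLoadings("hypo"))
  seek <- bifactorIndices(referenceLoadings("seek"))
  expect_equal(round(hyper@ecvG, 3), 0.436)
  expect_equal(round(hypo@ecvG, 3), 0.413)
  expect_equal(round(seek@ecvG, 3), 0.531)
  ssH <- as.data.frame(hyper@subscales)
  expect_equal(round(ssH$ecvSS[ssH$subscale == "Auditory"], 3), 0.619)
  expect_equal(round(ssH$ecvSS[ssH$subscale == "Tactile"], 3), 0.227)
  expect_equal(round(unlist(ssH[, c("ecvG", "ecvSS")]), 3),
               c(ecvG1 = 0.381, ecvG2 = 0.475, ecvG3 = 0.773, ecvG4 = 0.326,
                 ecvG5 = 0.460, ecvG6 = 0.322,
                 ecvSS1 = 0.619, ecvSS2 = 0.525, ecvSS3 = 0.227,
                 ecvSS4 = 0.674, ecvSS5 = 0.540, ecvSS6 = 0.678),
               ignore_attr = TRUE)
  itH <- as.data.frame(hyper@itemTable)
  expect_equal(round(itH$h2[1], 3), 0.752)
  expect_equal(round(itH$iecv[1], 3), 0.350)
  itP <- as.data.frame(hypo@itemTable)
  expect_equal(round(itP$h2[3], 3), 0.892)   # third hyporeactivity item
  expect_equal(round(itP$iecv[3], 3), 0.194)
  itS <- as.data.frame(seek@itemTable)
  expect_equal(round(itS$h2[1], 3), 0.645)   # first seeking item
  # the printed .740 comes from unrounded loadings; the 3-dp loadings give
  # .7406, a rounding-limited cell
  expect_equal(itS$iecv[1], 0.740, tolerance = 2e-3)
  # single-item indicator: communality from the general loading alone,
  # I-ECV exactly 1
  aud <- which(itP$item == "SEQ2 Q4/SEQ3 Q4 [Auditory]")
  expect_equal(round(itP$h2[aud], 3), 0.307)
  expect_equal(itP$iecv[aud], 1)
})

test_that("omega properties: unidimensional limit and permutation invariance", {
  L <- referenceLoadings("hyper")
  # all specific loadings zero: omegaH = omegaT, ECV_G = 1, every I-ECV = 1
  uni <- bifactorIndices(L$lambdaG, rep(0, length(L$lambdaG)),
                         rep(NA_character_, length(L$lambdaG)))
  expect_equal(uni@omegaH, uni@omegaT)
  expect_equal(uni@ecvG, 1)
  expect_true(all(as.data.frame(uni@itemTable)$iecv == 1))
  # permuting items (within and across subscales) leaves indices unchanged
  set.seed(33)
  perm <- sample(seq_along(L$lambdaG))
  permuted <- bifactorIndices(L$lambdaG[perm], L$lambdaS[perm],
                              L$structure[perm], L$items[perm])
  orig <- bifactorIndices(L)
  expect_equal(permuted@omegaT, orig@omegaT)
  expect_equal(permuted@omegaH, orig@omegaH)
  expect_equal(permuted@ecvG, orig@ecvG)
  ssP <- as.data.frame(permuted@subscales)
  ssO <- as.data.frame(orig@subscales)
  expect_equal(ssP[order(ssP$subscale), -1], ssO[order(ssO$subscale), -1],
               ignore_attr = TRUE)
})

test_that("index-set invariants hold and validity catches violations", {
  bi <- bifactorIndices(referenceLoadings("seek"))
  it <- as.data.frame(bi@itemTable)
  expect_equal(it$h2, it$lambdaG^2 + it$lambdaS^2)
  expect_true(all(it$iecv >= 0 & it$iecv <= 1))
  ss <- as.data.frame(bi@subscales)
  expect_equal(ss$ecvG + ss$ecvSS, rep(1, nrow(ss)))
})

test_that("interpretability rules follow both branches and the regime anchors", {
  mk <- function(omegaH, ecvG, omegaS = numeric(0), omegaHS = numeric(0),
                 ecvSS = numeric(0)) {
    ss <- data.frame(subscale = if (length(omegaS))
                       paste0("s", seq_along(omegaS)) else character(0),
                     omegaS = omegaS, omegaHS = omegaHS,
                     ecvG = 1 - ecvSS, ecvSS = ecvSS)
    new("BifactorIndexSet", omegaT = 0.95, omegaH = omegaH, ecvG = ecvG,
        subscales = S4Vectors::DataFrame(ss),
        itemTable = S4Vectors::DataFrame(item = character(0),
                                         lambdaG = numeric(0),
                                         lambdaS = numeric(0),
                                         structure = character(0),
                                         h2 = numeric(0), iecv = numeric(0)))
  }
  # published headline configurations drive the expected verdicts
  expect_identical(interpretabilityRules(mk(0.800, 0.436))$general, "strong")
  expect_identical(interpretabilityRules(mk(0.611, 0.413))$general,
                   "not supported")
  expect_identical(interpretabilityRules(mk(0.75, 0.65))$general, "strong")
  expect_identical(interpretabilityRules(mk(0.75, 0.55))$general,
                   "not supported")
  # high-reliability subscale with strong specific saturation adds value
  d <- interpretabilityRules(mk(0.611, 0.413, omegaS = 0.929,
                                omegaHS = 0.710, ecvSS = 0.781))
  expect_true(d$subscales$addedValue)
  expect_identical(d$subscales$regime, "high")
  # low-reliability regime uses the stricter bars
  d2 <- interpretabilityRules(mk(0.8, 0.5, omegaS = 0.62, omegaHS = 0.22,
                                 ecvSS = 0.40))
  expect_false(d2$subscales$addedValue)
  d3 <- interpretabilityRules(mk(0.8, 0.5, omegaS = 0.62, omegaHS = 0.26,
                                 ecvSS = 0.40))
  expect_true(d3$subscales$addedValue)
})
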