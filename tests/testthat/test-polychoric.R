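test_that("thresholds follow the closed form and flag degenerate columns", {
  # equal fifths over 5 categories
  x <- rep(1:5, each = 100)
  expect_equal(estimateThresholds(x), qnorm(c(0.2, 0.4, 0.6, 0.8)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # all responses in one category: no finite thresholds
  tau <- estimateThresholds(rep(1L, 50))
  expect_false(any(is.finite(tau)))
  expect_true(attr(tau, "degenerate"))
  expect_error(estimateThresholds(rep(NA_integer_, 10)), "all-missing")
})

test_that("thresholds are recovered from simulated data within Monte Carlo error", {
  set.seed(101)
  tauTrue <- c(-1, 0, 0.5, 1.5)
  n <- 5000
  x <- discretize(rnorm(n), tauTrue)
  tauHat <- estimateThresholds(x)
  # binomial SE of the cumulative proportion, transported through qnorm
  p <- pnorm(tauTrue)
  se <- sqrt(p * (1 - p) / n) / dnorm(tauTrue)
  expect_true(all(abs(tauHat - tauTrue) < 3 * se))
})

test_that("pairwise polychoric estimation handles canonical cases", {
  set.seed(102)
  # independence table: product margins
  x <- sample(1:5, 4000, TRUE)
  y <- sample(1:5, 4000, TRUE)
  expect_lt(abs(polychoricPair(x, y)$rho), 0.05)
  # comonotone relabeling reported at the boundary guard
  expect_equal(polychoricPair(x, x)$rho, 0.999)
  # 2x2 discretization of a rho = 0.5 bivariate normal
  n <- 10000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  pr <- polychoricPair((z1 > 0) + 1L, (z2 > 0) + 1L, nCategories = 2L)
  expect_lt(abs(pr$rho - 0.5), 0.05)  # ~3 SEs for a tetrachoric at this n
  # symmetry
  x5 <- discretize(z1, c(-1, 0, 1)); y5 <- discretize(z2, c(-0.5, 0.5, 1.2))
  expect_equal(polychoricPair(x5, y5)$rho, polychoricPair(y5, x5)$rho,
               tolerance = 1e-4)
})

test_that("bivariate-normal cell probabilities match the mvtnorm oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(103)
  for (rho in c(-0.7, 0, 0.4, 0.9)) {
    a <- runif(10, -2.5, 2.5); b <- runif(10, -2.5, 2.5)
    ref <- mapply(function(ai, bi)
      mvtnorm::pmvnorm(upper = c(ai, bi),
                       corr = matrix(c(1, rho, rho, 1), 2))[1], a, b)
    expect_equal(sensefactor:::.pbvn(a, b, rho), ref, tolerance = 1e-10)
  }
})

test_that("polychoric matrices converge to the generating structure", {
  set.seed(104)
  lam <- 0.7
  tau <- c(-1, -0.3, 0.3, 1)
  for (n in c(500, 5000)) {
    th <- rnorm(n)
    x <- sapply(1:3, function(j)
      discretize(lam * th + sqrt(1 - lam^2) * rnorm(n), tau))
    pm <- polychoricMatrix(x)
    off <- polyCor(pm)[upper.tri(diag(3))]
    tolMc <- 4 / sqrt(n)
    expect_true(all(abs(off - lam^2) < tolMc))
  }
  # mutually independent items give near-zero off-diagonals
  xi <- sapply(1:3, function(j) discretize(rnorm(2000), tau))
  expect_lt(max(abs(polyCor(polychoricMatrix(xi))[upper.tri(diag(3))])), 0.06)
})

test_that("a non-PSD pairwise matrix is repaired and flagged", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)  # eig < 0
  expect_lt(min(eigen(R)$values), 0)
  R2 <- sensefactor:::.nearPSDcor(R)
  expect_gte(min(eigen(R2)$values), -1e-10)
  expect_equal(diag(R2), rep(1, 3))
  # through the matrix API: construct ordinal data whose pairwise estimates
  # are PSD, then verify the flag machinery via the repaired path directly
  pm <- new("PolychoricResult", rho = R2, thresholds = list(),
            pairwiseN = matrix(0L, 3, 3), converged = matrix(TRUE, 3, 3),
            psdRepaired = TRUE, minEigenvalue = min(eigen(R)$values))
  expect_true(pm@psdRepaired)
})
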