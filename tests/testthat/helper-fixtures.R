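# Shared fixture builders. Everything is generated in code from fixed seeds.

# ordinal items from a one-factor (or bifactor) normal-ogive model with
# probit thresholds tau
discretize <- function(y, tau) findInterval(y, tau) + 1L

# persons x 6 matrix: items 1:4 load a planted unidimensional factor,
# items 5:6 are independent noise
plantedScaleBank <- function(seed, n = 1000) {
  set.seed(seed)
  th <- rnorm(n)
  lam <- c(0.75, 0.70, 0.72, 0.68)
  tau <- seq(-1.5, 1.5, length.out = 4)
  x <- matrix(NA_integer_, n, 6)
  for (j in 1:4)
    x[, j] <- discretize(lam[j] * th + sqrt(1 - lam[j]^2) * rnorm(n), tau)
  for (j in 5:6) x[, j] <- discretize(rnorm(n), tau)
  colnames(x) <- paste0("it", 1:6)
  x
}

# small two-instrument raw-response fixture with a 3-item crosswalk
toyRawData <- function() {
  bank <- ItemBank(
    items = data.frame(item_id = c("aud1", "aud2", "aud3"),
                       modality = "Auditory", response_pattern = "HYPER",
                       most_global = c(TRUE, FALSE, FALSE)),
    sourceCodes = data.frame(
      instrument = c("SP1", "SP1", "SEQ3", "SEQ3", "SEQ3"),
      code = c("Q1", "Q2", "Q11", "Q12", "Q13"),
      item_id = c("aud1", "aud2", "aud1", "aud2", "aud3")))
  raw <- list(
    SP1 = data.frame(person_id = c("p1", "p2"), Q1 = c(1L, 4L), Q2 = c(2L, NA)),
    SEQ3 = data.frame(person_id = c("p2", "p3"), Q11 = c(3L, 2L),
                      Q12 = c(5L, 1L), Q13 = c(4L, 4L)))
  list(bank = bank, raw = raw)
}

# multi-study data straight from the hierarchical IDA model (the sampler's
# own generative family, for calibration checks)
idaSimData <- function(r, tau1, S = 10, n = 200, seed = 1) {
  set.seed(seed)
  study <- rep(seq_len(S), each = n)
  rs <- r + rnorm(S, 0, tau1)
  x <- rnorm(S * n)
  y <- rs[study] * x + rnorm(S, 0, 0.3)[study] +
    rnorm(S * n, 0, sqrt(max(1 - r^2, 0.5)))
  list(y = y, x = x, study = study)
}

quadRef <- quadratureGrid()
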