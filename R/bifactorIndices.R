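# Bifactor model-based indices and the construct-interpretability rule
# engine. All indices are pure arithmetic on standardized loadings, so they
# apply equally to fitted solutions and to published loading tables.

#' Bifactor reliability and explained-common-variance indices
#'
#' From standardized bifactor loadings (general loading per item, at most one
#' specific loading per item) computes: omega total `omegaT = [(sum
#' lambdaG)^2 + sum_s (sum_{i in s} lambdaS)^2] / [same + sum(1 - h2)]`;
#' omega hierarchical `omegaH = (sum lambdaG)^2 / denominator`; per-subscale
#' `omegaS`/`omegaHS` with the sums restricted to the subscale's items (the
#' hierarchical-subscale coefficient is the specific factor's share of
#' subscale variance); explained common variance `ecvG = sum lambdaG^2 / sum
#' h2` overall and per subscale, with `ecvSS = 1 - ecvG(s)` within each
#' subscale; and per-item communalities `h2` and `I-ECV = lambdaG^2 / h2`.
#'
#' @param lambdaG numeric vector of general-factor loadings, or a
#'   [GrmSolution-class], or a list with `lambdaG`, `lambdaS`, `structure`
#'   (as returned by [referenceLoadings()]).
#' @param lambdaS specific-factor loadings (0 for general-only items).
#' @param structure character vector naming each item's specific factor
#'   (`NA` = general only).
#' @param items optional item labels.
#' @return a [BifactorIndexSet-class].
#' @export
bifactorIndices <- function(lambdaG, lambdaS = NULL, structure = NULL,
                            items = NULL) {
  if (is(lambdaG, "GrmSolution")) {
    sol <- lambdaG
    items <- sol@items
    structure <- sol@structure
    lambdaS <- sol@loadings[, "lambdaS"]
    lambdaG <- sol@loadings[, "lambdaG"]
  } else if (is.list(lambdaG) && !is.null(lambdaG$lambdaG)) {
    L <- lambdaG
    items <- L$items; lambdaS <- L$lambdaS; structure <- L$structure
    lambdaG <- L$lambdaG
  }
  p <- length(lambdaG)
  if (is.null(lambdaS)) lambdaS <- rep(0, p)
  if (is.null(structure)) structure <- rep(NA_character_, p)
  if (is.null(items)) items <- paste0("item", seq_len(p))
  lambdaS[is.na(structure)] <- 0
  h2 <- lambdaG^2 + lambdaS^2
  iecv <- ifelse(h2 > 0, lambdaG^2 / h2, NA_real_)
  subs <- unique(structure[!is.na(structure)])
  sumSpec2 <- sum(vapply(subs, function(s)
    sum(lambdaS[which(structure == s)])^2, numeric(1)))
  varTotal <- sum(lambdaG)^2 + sumSpec2 + sum(1 - h2)
  omegaT <- (sum(lambdaG)^2 + sumSpec2) / varTotal
  omegaH <- sum(lambdaG)^2 / varTotal
  ecvG <- sum(lambdaG^2) / sum(h2)
  ss <- do.call(rbind, lapply(subs, function(s) {
    i <- which(structure == s)
    varS <- sum(lambdaG[i])^2 + sum(lambdaS[i])^2 + sum(1 - h2[i])
    data.frame(subscale = s,
               omegaS = (sum(lambdaG[i])^2 + sum(lambdaS[i])^2) / varS,
               omegaHS = sum(lambdaS[i])^2 / varS,
               ecvG = sum(lambdaG[i]^2) / sum(h2[i]),
               ecvSS = sum(lambdaS[i]^2) / sum(h2[i]))
  }))
  if (is.null(ss)) ss <- data.frame(subscale = character(0),
                                    omegaS = numeric(0), omegaHS = numeric(0),
                                    ecvG = numeric(0), ecvSS = numeric(0))
  new("BifactorIndexSet", omegaT = omegaT, omegaH = omegaH, ecvG = ecvG,
      subscales = DataFrame(ss),
      itemTable = DataFrame(item = items, lambdaG = lambdaG,
                            lambdaS = lambdaS, structure = structure,
                            h2 = h2, iecv = iecv))
}

#' Construct-interpretability decision rules for bifactor indices
#'
#' General factor: "strong" when `omegaH >= 0.80`, or when `omegaH >= 0.70`
#' and `ecvG >= 0.60` jointly; otherwise "not supported". Subscale added
#' value: the reliability regime is chosen by whichever anchor (`omegaS`
#' approximately 0.60 vs 0.80) is nearer; in the low-reliability regime a
#' subscale adds value when `omegaHS >= 0.25` or `ecvSS >= 0.45`, in the
#' high-reliability regime when `omegaHS >= 0.20` or `ecvSS >= 0.30`.
#'
#' @param indices a [BifactorIndexSet-class].
#' @return list of class `DecisionOutcome`: `general` (`"strong"` /
#'   `"not supported"`), `subscales` (data.frame with per-subscale verdicts),
#'   and `ruleTrace` (character log of every comparison).
#' @export
interpretabilityRules <- function(indices) {
  stopifnot(is(indices, "BifactorIndexSet"))
  tr <- character(0)
  oh <- indices@omegaH; eg <- indices@ecvG
  strongA <- oh >= 0.80
  strongB <- oh >= 0.70 && eg >= 0.60
  tr <- c(tr, sprintf("general: omegaH = %.3f %s 0.80 -> %s", oh,
                      if (strongA) ">=" else "<",
                      if (strongA) "strong" else "check combination rule"))
  if (!strongA)
    tr <- c(tr, sprintf(
      "general: omegaH = %.3f, ECV_G = %.3f vs (>= 0.70 & >= 0.60) -> %s",
      oh, eg, if (strongB) "strong" else "not supported"))
  general <- if (strongA || strongB) "strong" else "not supported"
  ss <- as.data.frame(indices@subscales)
  if (nrow(ss)) {
    regime <- ifelse(abs(ss$omegaS - 0.60) <= abs(ss$omegaS - 0.80),
                     "low", "high")
    omegaHsMin <- ifelse(regime == "low", 0.25, 0.20)
    ecvSsMin <- ifelse(regime == "low", 0.45, 0.30)
    added <- ss$omegaHS >= omegaHsMin | ss$ecvSS >= ecvSsMin
    for (i in seq_len(nrow(ss)))
      tr <- c(tr, sprintf(
        "%s: omegaS = %.3f (%s-reliability regime), omegaHS = %.3f vs %.2f, ECV_SS = %.3f vs %.2f -> %s",
        ss$subscale[i], ss$omegaS[i], regime[i], ss$omegaHS[i],
        omegaHsMin[i], ss$ecvSS[i], ecvSsMin[i],
        if (added[i]) "added value" else "no added value"))
    ss$regime <- regime
    ss$addedValue <- added
  }
  structure(list(general = general, subscales = ss, ruleTrace = tr),
            class = "DecisionOutcome")
}

#' @export
print.DecisionOutcome <- function(x, ...) {
  cat("DecisionOutcome: general factor", x$general, "\n")
  if (nrow(x$subscales))
    print(x$subscales[, c("subscale", "omegaS", "omegaHS", "ecvSS",
                          "addedValue")])
  invisible(x)
}

#' Render a bifactor index table as Markdown
#'
#' Lays out per-item loadings, communalities and I-ECV with footer rows for
#' omega and ECV coefficients, mirroring the conventional bifactor loading
#' table layout.
#'
#' @param indices a [BifactorIndexSet-class].
#' @return character vector of Markdown lines.
#' @export
formatIndexTable <- function(indices) {
  it <- as.data.frame(indices@itemTable)
  ss <- as.data.frame(indices@subscales)
  subs <- ss$subscale
  hdr <- c("Item", "General", subs, "h2", "I-ECV")
  lines <- c(paste("|", paste(hdr, collapse = " | "), "|"),
             paste("|", paste(rep("---", length(hdr)), collapse = " | "), "|"))
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.3f", v))
  for (i in seq_len(nrow(it))) {
    cells <- vapply(subs, function(s)
      if (!is.na(it$structure[i]) && it$structure[i] == s)
        sprintf("%.3f", it$lambdaS[i]) else "-", character(1))
    lines <- c(lines, paste("|", paste(c(it$item[i], fmt(it$lambdaG[i]),
                                         cells, fmt(it$h2[i]),
                                         fmt(it$iecv[i])), collapse = " | "),
                            "|"))
  }
  foot <- function(label, gen, vals)
    paste("|", paste(c(label, fmt(gen), fmt(vals), "", ""), collapse = " | "),
          "|")
  lines <- c(lines,
             foot("omegaT/omegaS", indices@omegaT, ss$omegaS),
             foot("omegaH/omegaHS", indices@omegaH, ss$omegaHS),
             foot("ECV_G", indices@ecvG, ss$ecvG),
             foot("ECV_SS", NA, ss$ecvSS))
  lines
}
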