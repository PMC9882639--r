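---
title: "Models and methods behind sensefactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sensefactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sensefactor` implements a complete psychometric pipeline for pooled
(multi-study) analyses of caregiver-reported sensory reactivity items:
harmonization of analogous questionnaire items across instrument versions,
polychoric correlation of the resulting ordinal matrix, graded-response
measurement models (unidimensional and bifactor), iterative scale
refinement, supra-modal structure evaluation with bifactor indices and
decision rules, and a Bayesian random-effects correlate analysis. This
vignette documents the models, the numerical choices, and the design
decisions that were genuinely open, in one place.

## The data model

Ordinal item responses live in a `SensoryExperiment`, a
`SummarizedExperiment` with items as rows and persons as columns. Observed
codes are integers in `1..K` (K = 5 throughout the questionnaire family
targeted here); `NA` marks *planned* missingness: a person only has values
for items sourced from instruments their study administered. This
missingness is structural, so a distinct sentinel (`NA`, never a category
code) is kept and nothing is imputed; every downstream likelihood simply
skips unobserved entries, and correlations use pairwise deletion (listwise
deletion would discard nearly everyone in a pooled sample where
instruments barely overlap).

Harmonization merges instrument-specific codes into one item via the
`ItemBank` crosswalk. Instruments scored in the reverse direction (the
first Sensory Profile and its short form) are flipped as `k -> K + 1 - k`,
an involution, so that 5 always means "more frequent". When a person has
observed values from two instruments for one harmonized item, the
SEQ-family value is kept and the conflict logged; the SEQ carries more
items of the bank, and pooling at item level otherwise provides no
principled tie-break. Age eligibility is the closed interval \[3, 18\]
years — "3 years 0 months to 18 years 0 months" reads as inclusive at
both ends — and persons with missing age are retained.

## Polychoric correlations

For each item, thresholds are the standard-normal quantiles of the
cumulative category proportions. For each pair, the latent correlation
maximizes the bivariate-normal cell likelihood with thresholds fixed at
their univariate estimates (two-stage estimation; full ML buys little here
at pooled sample sizes and costs an order of magnitude more). The
bivariate normal CDF is evaluated by 64-node Gauss–Legendre quadrature of
`phi(x) * Phi((b - rho*x)/sqrt(1-rho^2))`, accurate to ~1e-12 (the test
suite cross-checks against an independent multivariate-normal
implementation). Estimates are guarded at `|rho| <= 0.999` so factor
routines downstream keep finite information, and a non-positive-definite
pairwise matrix (possible under pairwise deletion) is repaired by
eigenvalue clipping and flagged.

## Graded response models

The measurement model is the logistic graded response model: for item $j$
with ordered categories $1..K$,
$$P(X_j > k \mid \theta) = \mathrm{logit}^{-1}(a_j^\top \theta + c_{jk}),
\qquad c_{j1} > \dots > c_{j,K-1}.$$
Slopes convert to standardized loadings through the conventional
logistic–probit bridge $a^* = a/1.702$,
$\lambda_d = a^*_d / \sqrt{1 + \sum_d a^{*2}_d}$; the map is inverted
exactly when simulating from published loading tables.

Estimation is Bock–Aitkin marginal maximum likelihood EM under a standard
normal latent prior, on a fixed grid of 49 equally spaced nodes on
\[-6, 6\] with normalized normal weights — enough for 5-category items,
and fixed so that results are deterministic given the data. The M-step
solves each item's expected complete-data problem by a few quasi-Newton
steps with an analytic gradient, in a parameterization (leading intercept
plus log-gaps) that keeps intercepts ordered; partial inner maximization
makes this a generalized EM, which still increases the likelihood every
cycle. Convergence is declared when the largest absolute parameter change
falls below `tol` (default 1e-5, capped at 500 cycles; hitting the cap
flags the solution rather than failing). An extrapolation accelerator
(SQUAREM-style) is applied in the unconstrained parameter space; every
accelerated jump is accepted only if the next E-step confirms the
log-likelihood did not decrease, so the recorded likelihood history is
monotone by construction, and the suite asserts it.

The confirmatory bifactor model gives every item a general slope and at
most one specific slope (simple structure). The marginal likelihood uses
the bifactor dimension reduction: conditional on the general factor, the
specific factors are independent across item groups, so each integrates
out separately and the cost is $O(Q^2 \cdot \text{items})$ instead of
$O(Q^{1+S})$. The factorization is exact — a test compares it with
brute-force two-dimensional quadrature to 1e-6 relative error (observed:
1e-16). Within each group, persons are collapsed to their distinct
group-response patterns (missingness included) before the $Q^2$
computation, which is what makes fits at $n = 3000$ practical in plain R.
Specific factors are reflection-identified by fixing each specific slope
sum to be positive. Single-item subconstruct indicators must load on the
general factor only; a specific factor with fewer than two items is
rejected at validation.

EAP scores are posterior means on the same grid; for bifactor solutions
the general factor integrates the specifics out by the same identity, and
each specific factor integrates out the general. A person with no
observed items receives the prior (mean 0, SD 1) and is flagged. Marginal
reliability is $\rho_{xx} = 1 - \overline{\mathrm{SD}^2_{post}}$ under the
unit prior.

Two total-score reliabilities are exposed, because they answer different
questions: `omegaCategorical()` (Green–Yang) propagates loadings *and*
thresholds through bivariate-normal category probabilities and is the
default for data work, while `omegaFromLoadings()` is the simple
standardized-loading formula used for reproducing published loading-table
coefficients. Published omega cells are not recoverable from rounded
loadings (discrepancies of 0.01–0.03 are typical), so omega is verified by
structural properties (unidimensional limit, permutation invariance)
rather than by matching printed values.

### Limited-information fit

SRMR is the root mean square of lower-triangle differences between the
sample polychoric matrix and the model-implied correlations
$\Lambda\Lambda^\top + \mathrm{diag}(1-h^2)$. Approximate RMSEA and TLI
come from a residual-based quadratic form $T = n\sum r^2$ with
$df = p(p-1)/2 - \#\text{free loadings}$ and an independence null. The
exact C2 limited-information statistic is deliberately not replicated: its
weight matrix depends on implementation details that are not public, and
every retention decision in the refinement loop rides on the thresholds,
SRMR, and the reliabilities, which are implemented faithfully. With
$df \le 0$ (a just-identified 3-item scale) only SRMR is reported.

## Scale refinement

`refineScale()` operationalizes the iterative single-subconstruct
procedure: (1) cluster the candidate items on polychorics with `iclust()`
and keep the largest cluster with at least three items (skipped when the
pool is exactly three — nothing could be pruned); (2) fit the
unidimensional GRM; (3) evaluate TLI > 0.97, RMSEA < 0.089, SRMR < 0.05
(< 0.033 at exactly three items, where TLI/RMSEA are undefined),
$\rho_{xx} > 0.7$ and $\omega_T > 0.7$; (4) on failure remove the item
with the largest maximum absolute residual correlation, ties broken by
the lowest loading; (5) stop on success, or fall back to a single item
when fewer than three items remain or a removal stops improving SRMR.
The fallback item is a bank annotation (`most_global`), encoding an
expert choice as data so the pipeline stays reproducible.

`iclust()` merges clusters in decreasing order of unit-weight composite
correlation. The merged cluster's beta is the Spearman–Brown stepped-up
correlation of its two merging halves — the natural worst split at that
node (exhaustive split-half search is exponential, and order-based splits
add bookkeeping without changing any decision on the structures at hand).
The acceptance rule was the one genuinely open design choice. Requiring
the merged beta to be at least the *smaller* candidate's beta fails in
both directions: a chance-level junk pair (beta near 0.05) lowers the bar
so far that distractors ride into the main cluster, while homogeneous
clusters are blocked from growing because beta legitimately fluctuates
downward. The implemented rule — the merged beta may not fall more than
`betaSlack = 0.15` below the *better* candidate's beta, and the
inter-composite correlation must be positive — separates the two regimes
cleanly: legitimate growth in reference structures with heterogeneous
specific loadings (drops up to ~0.13) passes, while chance-level
attachments (beta ~0.1 against bars of ~0.6) are refused. Single items
carry no beta, so item–item merges need only a positive correlation,
which also yields the textbook two-item result
$\beta = 2r/(1+r) = 0.889$ at $r = 0.8$ and no merges on an identity
matrix.

## Structure evaluation

The supra-modal stage fits a one-factor CFA to the per-modality EAP
scores (maximum-likelihood discrepancy for continuous scores; unweighted
least squares on the polychoric matrix for ordinal/mixed indicators, with
a residual-based quadratic form in place of the ML chi-square). Robust
(sandwich-type) corrections to the ML chi-square are not implemented:
they require case-level fourth-moment machinery and change none of the
decisions, which key on CFI/RMSEA/SRMR magnitudes. If the initial model
(scores plus single-item indicators) fits poorly, the pipeline can re-fit
without the single-item indicators — the generalization of the
seeking-domain re-fit rule, exposed as the `refit = "auto"` option.

Exploratory graph analysis estimates a regularized partial-correlation
network by graphical lasso over a 20-point log-spaced penalty grid, picks
the penalty by EBIC with $\gamma = 0.5$, and detects communities with
4-step Walktrap on absolute edge weights — canonical EGA defaults. An
empty selected graph leaves every item in its own community, flagged.

`bifactorIndices()` computes, from standardized loadings alone:
$\omega_T$, $\omega_H$, per-subscale $\omega_S$ and $\omega_{HS}$ (the
specific factor's share of subscale variance), $ECV_G$ overall and per
subscale, $ECV_{SS}$, and per-item $h^2$ and I-ECV. Applied to the
packaged reference loading tables these reproduce the published
explained-common-variance cells — exactly for the 23-item
hyperreactivity table and the per-item cells the acceptance script
reports; a handful of cells in the other tables differ by 0.001–0.006
because the printed loadings are themselves rounded to three decimals
(the published values were evidently computed from unrounded ones). Those
rounding-sensitive cells are not asserted anywhere.

`interpretabilityRules()` encodes the decision framework: a strong
general factor needs $\omega_H \ge .80$, or $\omega_H \ge .70$ together
with $ECV_G \ge .60$; a subscale has added value when
$\omega_{HS} \ge .25$ or $ECV_{SS} \ge .45$ in the low-reliability regime
($\omega_S$ near .60), or $\omega_{HS} \ge .20$ or $ECV_{SS} \ge .30$ in
the high-reliability regime (near .80). The rules are stated only at the
two anchors, so the regime is chosen by whichever anchor $\omega_S$ is
nearer (cut at 0.70); every comparison is logged in the rule trace.

## Bayesian random-effects IDA

Each interpretable score is regressed on one correlate at a time:
$$y_{is} = \beta_0 + \beta_1 x_{is} + u_{0s} + u_{1s} x_{is} +
\varepsilon_{is},\quad u_{0s}\sim N(0,\tau_0^2),\ u_{1s}\sim N(0,\tau_1^2),
\ \varepsilon\sim N(0,\sigma^2),$$
with the outcome standardized on the pooled sample and continuous
correlates standardized (so $\beta_1$ is the correlation $r$) or binary
correlates coded 0/1 (so $\beta_1$ is Cohen's $d$). Random intercept and
slope are independent — only the two variance components enter any
reported quantity. Priors are weakly informative stand-ins (the original
specification is not public): $N(0,1)$ on standardized slopes and
half-$t_3$ with scales 0.5 (random-effect SDs) and 1.0 (residual SD), all
configurable. The half-$t$ priors use the Huang–Wand inverse-gamma
mixture, which makes the model fully conditionally conjugate; the
sampler is a blocked Gibbs sampler driven entirely by per-study
sufficient statistics, with the fixed effects drawn from their
*collapsed* conditional (random effects integrated out analytically via
Woodbury on 2x2 blocks). The collapsed update matters: the naive sampler
leaves 95% HDI coverage at 0.92 with frequent split-Rhat failures, the
collapsed one is calibrated (coverage 0.94–0.96) with none. A test
cross-checks the posterior of $\beta_1$ against an independent
JAGS fit of the same model (agreement to ~0.005 in the median). Four
chains are run; summaries are refused when split-Rhat on the slope
reaches 1.01, and models with fewer than 100 complete pairs are refused
outright with a recorded reason.

Effect sizes are summarized by the posterior median and the 95%
highest-density interval (shortest sorted-draw window; verified in tests
against an exhaustive interval search). The interval null uses the
region of practical equivalence $r \in [-0.1, 0.1]$ and
$d \in [-0.2, 0.2]$ — the asymmetric interval printed in one source text
is read as a typo for the symmetric one, and the bounds are arguments.
$\log BF_{ROPE}$ compares posterior to prior odds of lying outside
versus inside the ROPE, with the prior mass computed analytically from
the normal effect prior and posterior proportions clipped to
$[1/(4n), 1 - 1/(4n)]$; positive values are evidence for a practically
meaningful effect, with moderate/strong boundaries at $\log 3$ and
$\log 10$. Heterogeneity is reported as $\tau^2$ (and $\tau$, since
"variance in SD units" is ambiguous — both are emitted), $I^2 =
\tau_1^2/(\tau_1^2 + \bar v)$ with $\bar v$ the mean study-level sampling
variance of the slope, the ICC
$(\tau_0^2 + \tau_1^2\,\mathrm{Var}(x)) / (\tau_0^2 +
\tau_1^2\,\mathrm{Var}(x) + \sigma^2)$, and a 95% prediction interval
from $\beta_1 + u_{1,\text{new}}$ draws.

## The synthetic-data generator

`simulateSensoryData()` emulates the statistical structure of a pooled
consortium sample: around a dozen studies (default 12) with sizes drawn
log-uniformly between 30 and 1300; latent general and specific traits as
independent standard normals, the general trait shifted per study by
$N(0, 0.4^2)$ (putting roughly 10–20% of trait variance between studies,
the range reported for pooled sensory scores); item categories drawn from
the bifactor GRM implied by a loading table (default: the
hyperreactivity reference table) with thresholds evenly spaced on
\[-2, 2\] (no thresholds are published; the default is overridable);
structural missingness by per-study instrument-coverage patterns; and
correlates built as linear combinations of the general trait and
independent noise calibrated analytically to a target population $r$ (or
group shift $d$), with per-study effects varying around the target with
SD $\tau_1$. Ground truth (latent traits, generating loadings, per-study
effects) is returned alongside the data, and everything is reproducible
from one seed.

What the generator does *not* emulate: real SP/SEQ marginal
distributions, differential item functioning between instrument
versions, non-normal latent traits, or correlated specific factors.
Passing tests therefore demonstrate that the pipeline's estimators and
decisions are correct *under the stated model family* — not that any
particular real dataset satisfies that family.

## Problem sizes in the test suite

Simulation sizes were chosen to keep each check informative at desk
scale: the bifactor recovery check fits the 11-item reference structure
once at $n = 3000$ (loading RMSE $\le 0.05$; observed ~0.014); planted
4-item scale recovery uses 20 replicates at $n = 1000$ ($\ge 80\%$ exact
recovery required); graph-analysis checks use $n = 1000$ with 20
replicates for the speech-community finding; sampler calibration uses
200 replicates of 10 studies x 200 persons with 2000 posterior draws
(coverage within \[93%, 97%\] for true $r \in \{0, 0.3\}$); end-to-end
determinism runs the full pipeline twice at 5 studies x 150 persons and
compares artifact hashes. Unit tests use smaller sizes with tolerances
set from the corresponding Monte-Carlo standard errors.

## Known limitations

- The refinement removal rule (largest maximum absolute residual, ties
  by lowest loading) and the ICLUST acceptance rule are explicit,
  deterministic stand-ins for procedures whose original settings are not
  public; both are documented above and easy to swap.
- Approximate RMSEA/TLI are not the C2-based statistics; they share the
  retention thresholds but not the exact sampling distribution.
- The CFA estimator is plain ML (or ULS on polychorics) without robust
  corrections.
- The IDA stage fits unconditional bivariate models only — no covariate
  adjustment, no nonlinearities — and its priors are stand-ins.
- Items with categories never observed in a fitted subsample keep their
  nominal category count; their outer intercepts are weakly identified
  (bounded, flagged via the Heywood check when extreme).
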