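---
title: "Methods: graded response model CAT for ordinal outcome measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graded response model CAT for ordinal outcome measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemcat)
```

## The measurement model

pemcat measures a single latent trait $\theta$ (here: hand function, in
logits) from ordinal questionnaire items under Samejima's graded response
model (GRM). Item $i$ with $K_i$ ordered categories has a discrimination
$a_i > 0$ and strictly increasing boundary locations
$b_{i1} < \dots < b_{i,K_i-1}$. The probability of responding in category
$k$ or above is logistic,

$$P(X_i \ge k \mid \theta) = \frac{1}{1 + e^{-a_i(\theta - b_{i,k-1})}},
\qquad k = 2, \dots, K_i,$$

and category probabilities are adjacent differences of these boundaries.
We work in the pure logistic metric (scaling constant $D = 1$), the
convention of the dominant GRM software; a bank calibrated in the
normal-ogive-equivalent metric ($D = 1.7$) can be re-anchored by scaling
its slopes before import. Item Fisher information is the expected form
$I_i(\theta) = \sum_k (\partial P_{ik}/\partial\theta)^2 / P_{ik}$, the
standard choice for adaptive item selection, and test information is its
sum over administered items (local independence).

The model assumes unidimensionality and local independence. Neither is
tested formally here: `residuals.grm()` reports observed versus
model-expected category counts with Pearson residuals as a generic
goodness-of-fit diagnostic, and named item-fit or dimensionality
statistics are deliberately out of scope.

## Person scoring

Persons are scored by expected a posteriori (EAP) estimation: the
posterior mean of $\theta$ under a standard-normal population prior, with
the posterior standard deviation as the standard error of measurement
(SEm). EAP was chosen over maximum likelihood because it is finite for
extreme all-lowest/all-highest response patterns, it is the convention of
the PROMIS instruments whose precision threshold the stopping rule
borrows, and it gives the signature behaviour of a CAT trace: before any
item is answered the estimate *is* the population average.

The posterior is integrated on 481 equally spaced nodes over $[-6, 6]$
with normal prior weights. With very discriminating items (slopes around
5) the posterior can be narrow, and 161 nodes leave a quadrature error of
a few times $10^{-6}$ in the posterior SD for extreme patterns; 481 nodes
push the error below $10^{-6}$ in both moments at negligible cost, which
is far below any reporting precision. Category probabilities are clipped
to $[10^{-12}, 1 - 10^{-12}]$ before logs so that extreme $\theta$ values
cannot produce $-\infty$; the clip is orders of magnitude below anything
that affects test-level results.

Scores are reported on a 0--100 scale through an affine transform
attached to the item bank, $\mathrm{score} = s\,\theta + o$ clipped to
$[0, 100]$, with $\mathrm{SE} = s \times \mathrm{SEm}$ (pre-clip). The
default maps $[-4, 4]$ logits to $[0, 100]$ ($s = 12.5$, $o = 50$). The
transform is bank metadata, not a package constant, because a published
instrument's anchoring must travel with its parameters to reproduce its
printed scores.

## The adaptive test

`administer_cat()` loops select--ask--record--check:

* **Selection**: the unadministered item with maximal Fisher information
  at the current EAP point estimate; ties break to the lowest bank index,
  so selection is fully deterministic. Because every session starts at the
  prior mean, the first item is a constant of the bank.
* **Update**: after each response the EAP estimate is recomputed from all
  responses so far; the per-step trace is kept for plotting.
* **Stopping**: strictly $\mathrm{SEm} < 0.3$ on the *logit* scale (the
  PROMIS-style precision convention; a reliability of about 0.91),
  after at least `min_items` items. `min_items` defaults to 1: any
  observed floor of two or more items should emerge from the information
  content of the bank, not from a configured minimum. Exhausting the bank
  or hitting `max_items` also stops, with the reason recorded.

With an unreachable threshold the CAT administers every item and its
estimate equals the full-length EAP score exactly (same arithmetic path),
which the tests assert — this is the exhaustive-limit identity that
anchors the whole engine.

## Calibration

`grm()` estimates item parameters by marginal maximum likelihood with the
Bock--Aitkin EM algorithm. The latent density is fixed to standard normal
(the identification constraint; cohort-specific trait distributions are
handled downstream in simulation, not by rescaling the calibration). The
E-step evaluates each person's posterior over 61 Gauss--Legendre nodes on
$[-6, 6]$; the M-step maximizes each item's expected complete-data
log-likelihood by BFGS on $(\log a,\; b_1,\; \log \Delta b)$, a
reparameterization under which slope positivity and threshold ordering
hold by construction. The inner BFGS is capped (a generalized EM step)
and an update is only accepted if it does not decrease the objective, so
the marginal log-likelihood is non-decreasing across iterations — a
property the tests check to $10^{-8}$. Convergence is declared when the
marginal log-likelihood changes by less than `tol` (default $10^{-5}$);
non-convergence returns with `converged = FALSE` and a warning, never
silently.

Starting values are the classic ones: unit slopes and thresholds at
normal quantiles of the observed cumulative category proportions.
Missing responses are dropped from the per-person likelihood product
(missing at random); calibration on complete response sets only is a
reader-side flag (`read_responses(..., complete_cases = TRUE)`).
Categories never observed in the data have inestimable thresholds and are
collapsed into their nearest observed neighbour (lower neighbour on
ties), with a warning and a recorded category map so that new data coded
on the declared scale still score correctly through `predict.grm()`.
Fits with fewer persons than free parameters are refused outright rather
than returned half-identified.

## The Monte Carlo evaluation

`cat_simulate()` reproduces the standard CAT validation experiment: draw
$n$ true traits, simulate one complete response set per respondent from
the GRM category probabilities, score it once with all items
(full-length arm) and once by replaying the CAT against the same
responses (paired design — required for the agreement analysis). The
default cohort size is 1000 respondents.

True traits can be drawn standard normal, normal on the 0--100 score
scale back-transformed through the bank transform, or resampled from an
empirical score set. The score-scale normal matched to a published cohort
summary (mean 43.9, SD 18.7 for the surgical cohort this package's
evaluation emulates) is the default replication choice because registry
score distributions are typically summarized, not deposited.

`agreement_report()` computes, on the 0--100 scale with differences
oriented CAT $-$ full-length: mean error, mean absolute error, RMSE,
Pearson's $r$, ICC and the $R^2$/intercept/slope from regressing CAT on
full-length scores, and Bland--Altman limits of agreement
$\bar d \pm 1.96\,\mathrm{SD}(d)$. The ICC variant is ICC(A,1) — two-way
model, absolute agreement, single measurement — the standard choice for
method-agreement designs; it is computed from the mean-square
decomposition and cross-checked in the tests against an independent
ANOVA oracle. If either arm has zero variance the correlation-type
metrics are returned as flagged `NA` rather than propagated `NaN`.

## What the synthetic data do and do not show

The fixture generator (`make_fixture_bank()`,
`make_fixture_responses()`) emits 10-item, 7-category banks with slopes
log-uniform on $[0.9, 3]$ and spread thresholds — a generic short ordinal
instrument for exercising calibration and the engine.

`pem_synthetic_bank()` is a fixed, clearly labelled *synthetic stand-in*
for the calibrated 10-item Patient Evaluation Measure. Its item wordings
are the PEM's; its parameters are not a published calibration. They were
constructed once, from first principles, to reproduce the documented
informativeness profile of the calibrated instrument in an ulnar-nerve
surgical cohort: the everyday-activities item dominates (slope 5.2),
the work item is a close second (4.9), mid-tier function items follow,
and the two appearance items carry little information; thresholds centre
just below the cohort mean. Under this bank the evaluation shows the
qualitative signature of the real instrument — median two items at
median SEm 0.27, near-zero mean error, correlations above 0.99 — but its
absolute error magnitudes (MAE, RMSE, limits of agreement) are smaller
than a real calibration would give, because ideal GRM responses contain
none of the misfit, multidimensionality or response styles of registry
data. Passing tests on synthetic data therefore validate the engine's
arithmetic and contracts, not the clinical performance of any deployed
instrument.

## Numerical choices and edge cases

* EAP quadrature: 481 equally spaced nodes on $[-6, 6]$ (see above);
  calibration quadrature: 61 Gauss--Legendre nodes on $[-6, 6]$.
* Probability floor $10^{-12}$ before logarithms.
* Stopping inequality strict; ties in item selection to the lowest bank
  index; category-collapse ties to the lower neighbour.
* Thresholds are serialized at full double precision; bank files
  round-trip losslessly. A slope--intercept dialect
  ($P = \sigma(a\theta + d_k)$) is converted on load via $b_k = -d_k/a$.
* Empty response sets are legal everywhere and yield the prior.

Problem sizes in the test suite were chosen to exercise the asymptotics
that matter while staying quick: parameter recovery uses 1000 simulated
respondents on a 10-item bank; the exhaustive-limit and agreement
convergence checks use cohorts of 100--200; distribution checks use
$10^5$ draws.

## Known limitations

Unidimensional GRM only — no partial-credit or nominal models, no
multidimensional CAT, no exposure control or content balancing, no DIF or
formal assumption testing. Calibration assumes a normal latent density;
strongly non-normal populations will distort thresholds. The synthetic
stand-in bank must not be used to score real questionnaire responses.
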