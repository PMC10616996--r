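# pemcat

Graded response model (GRM) calibration, scoring and computerized
adaptive testing (CAT) for ordinal patient-reported outcome measures,
with a Monte Carlo harness for validating a CAT against full-length
scoring.

Long questionnaires burden patients and depress completion rates. If an
instrument fits a unidimensional item response theory model, a CAT can
administer only the most informative items for each respondent and stop
as soon as the trait estimate is precise enough, typically cutting the
instrument to a fraction of its length with near-identical scores. This
package implements that pipeline end to end for short ordinal
instruments such as the 10-item Patient Evaluation Measure (PEM) used in
hand surgery: it is aimed at psychometricians and outcomes researchers
who want to calibrate an item bank, simulate CAT performance, and deploy
the administration loop.

## The model

Item $i$ with $K_i$ ordered categories has discrimination $a_i$ and
thresholds $b_{i1} < \dots < b_{i,K_i-1}$ (logits, $D = 1$):

$$P(X_i \ge k \mid \theta) = \mathrm{logit}^{-1}\big(a_i(\theta - b_{i,k-1})\big),
\qquad P(X_i = k) = P(X_i \ge k) - P(X_i \ge k + 1).$$

* **Calibration** — `grm()`: Bock–Aitkin marginal maximum likelihood EM
  with a standard-normal latent density, returning a classed fit with
  `print`, `summary`, `coef`, `logLik`, `residuals`, `predict` and
  `simulate` methods.
* **Scoring** — `eap_estimate()`: expected a posteriori estimate of
  $\theta$ with the posterior SD as the standard error of measurement
  (SEm), reported both in logits and on a 0–100 scale via the bank's
  affine transform.
* **CAT** — `administer_cat()`: maximum-Fisher-information item
  selection at the current estimate, re-estimation after every response,
  stopping when SEm $< 0.3$ (strict, logit scale).
* **Evaluation** — `cat_simulate()` + `agreement_report()`: paired
  simulation of CAT versus full-length scores with mean error, MAE,
  RMSE, Pearson r, ICC(A,1), regression $R^2$, and Bland–Altman 95%
  limits of agreement; `usage_table()` gives per-item administration
  frequencies.

## Worked example

The package ships a synthetic stand-in bank shaped like the 10-item PEM
(`pem_synthetic_bank()`; item wordings are the PEM's, parameters are
synthetic — see the methods vignette). Administer a CAT to one simulated
respondent:

```r
library(pemcat)
bank <- pem_synthetic_bank()
responses <- structure(rep(4L, 10), names = names(bank$items))
administer_cat(bank, responses)
#> Adaptive test: 2 of 10 candidate items administered (stop: precision_met)
#> theta = -0.445 (SEm 0.255) | score 0-100 = 44.4 (SE 3.2) | 2 items
#> Trace:
#>  step item_id response  theta    se score
#>     1      Q7        4 -0.436 0.358  44.5
#>     2      Q8        4 -0.445 0.255  44.4
```

Two items (everyday-activities, then work) push the SEm below 0.3; the
score starts at the population average (50) and settles at 44.4. Now the
cohort experiment — 1000 respondents drawn from a trait distribution
with mean 43.9 and SD 18.7 on the 0–100 scale:

```r
sim <- cat_simulate(bank, n = 1000,
                    dist = theta_dist("score_normal", 43.9, 18.7), seed = 1)
summary(sim)
#> Agreement between CAT and full-length scores (n = 1000)
#>   Items administered: median 2 (IQR 2-5, range 2-10); median SEm 0.27
#>   Scores: CAT mean 44.3 (SD 17.2) vs full-length mean 44.2 (SD 17.5)
#>   Mean error 0.07 | MAE 1.37 | RMSE 1.91
#>   Pearson r 0.99 | ICC(A,1) 0.99 | regression R^2 0.99 (intercept 0.93, slope 0.98)
#>   Bland-Altman: mean difference 0.07, 95% LoA [-3.66, 3.81]
```

The CAT typically needs two of the ten items, keeps the SEm at a median
of 0.27, and reproduces the full-length score with a mean error of 0.07
score points. Calibration runs the other way — recover parameters from
response data:

```r
fx  <- make_fixture_responses(bank, 1000, seed = 11)
fit <- grm(fx$responses)
coef(fit)        # discriminations and thresholds, logits
plot(fit)        # item information curves
```

Item banks and response sets travel as JSON and CSV
(`read_item_bank()`, `read_responses()`, …), and
`inst/cli/pemcat-cli.R` wraps the pipeline in `calibrate` / `simulate` /
`evaluate` / `cat` / `make-fixtures` subcommands, including an
interactive console administration.

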