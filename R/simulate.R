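#' Latent-trait distributions for simulation
#'
#' Specifies how true latent traits are drawn for a simulated cohort:
#' \describe{
#'   \item{`"normal"`}{normal on the logit scale (`mean`, `sd` in logits);
#'     the default `mean = 0, sd = 1` is the calibration population.}
#'   \item{`"score_normal"`}{normal on the reported 0--100 scale
#'     (`mean`, `sd` in score points), back-transformed to logits through
#'     the bank's [scale_transform()]. This is the natural way to match a
#'     published cohort summary when only score-scale moments are known.}
#'   \item{`"empirical"`}{resampling with replacement from a supplied
#'     vector of logit values.}
#' }
#'
#' @param type one of `"normal"`, `"score_normal"`, `"empirical"`.
#' @param mean,sd moments (logits for `"normal"`, score points for
#'   `"score_normal"`).
#' @param values numeric vector for `"empirical"`.
#' @return An object of class `"theta_dist"`.
#' @export
theta_dist <- function(type = c("normal", "score_normal", "empirical"),
                       mean = 0, sd = 1, values = NULL) {
  type <- match.arg(type)
  if (type == "empirical" && (is.null(values) || length(values) == 0L))
    stop("`empirical` requires a non-empty `values` vector")
  if (type != "empirical" && (!is.finite(mean) || !is.finite(sd) || sd < 0))
    stop("`mean` and `sd` must be finite with sd >= 0")
  structure(list(type = type, mean = mean, sd = sd, values = values),
            class = "theta_dist")
}

#' Draw true latent traits for a simulated cohort
#'
#' @param n number of respondents.
#' @param dist a [theta_dist()].
#' @param transform the bank's [scale_transform()], needed to back-transform
#'   a `"score_normal"` specification to logits.
#' @return Numeric vector of length `n` (logits). Uses the current RNG
#'   state; seed upstream (e.g. in [cat_simulate()]) for reproducibility.
#' @export
generate_thetas <- function(n, dist = theta_dist(), transform = scale_transform()) {
  if (!inherits(dist, "theta_dist")) stop("`dist` must be a theta_dist()")
  switch(dist$type,
    normal = stats::rnorm(n, dist$mean, dist$sd),
    score_normal = (stats::rnorm(n, dist$mean, dist$sd) - transform$offset) /
      transform$slope,
    empirical = dist$values[sample.int(length(dist$values), n, replace = TRUE)])
}

#' Simulate full-length response sets from an item bank
#'
#' Draws one ordinal category per item and respondent from the GRM category
#' probabilities at the respondent's true latent trait.
#'
#' @param bank an [item_bank()].
#' @param theta numeric vector of true latent traits (one per respondent).
#' @return Integer matrix `length(theta) x n_items` with item-id columns.
#' @export
simulate_responses <- function(bank, theta) {
  n <- length(theta)
  out <- matrix(NA_integer_, n, length(bank$items),
                dimnames = list(NULL, names(bank$items)))
  for (i in seq_along(bank$items)) {
    K <- bank$items[[i]]$n_categories
    P <- category_probabilities(bank$items[[i]], theta)  # n x K
    cum <- t(apply(P, 1L, cumsum))[, -K, drop = FALSE]   # n x (K-1)
    out[, i] <- 1L + rowSums(stats::runif(n) > cum)      # inverse-CDF draw
  }
  out
}

#' Monte Carlo evaluation of a CAT against full-length scoring
#'
#' The simulated administration experiment: for each of `n` respondents a
#' true latent trait is drawn, a complete response set is simulated once,
#' the full-length EAP score is computed from all items, and the adaptive
#' test is replayed against the same responses (paired design). The result
#' collects one record per respondent for the agreement analysis and the
#' item-usage table.
#'
#' @param bank an [item_bank()].
#' @param n number of simulated respondents (default 1000).
#' @param dist a [theta_dist()] for the true traits.
#' @param control a [cat_control()].
#' @param grid quadrature from [eap_grid()].
#' @param seed optional integer seed; all randomness in the run flows from
#'   it.
#' @return An object of class `"cat_sim"`: list with `records` (data.frame,
#'   one row per respondent: true theta, full-length and CAT estimates on
#'   both scales, items used, stop reason), `items_administered` (list of
#'   per-respondent item-id vectors), plus the bank and configuration.
#' @examples
#' sim <- cat_simulate(pem_synthetic_bank(), n = 50, seed = 1)
#' summary(sim)
#' @export
cat_simulate <- function(bank, n = 1000, dist = theta_dist(),
                         control = cat_control(), grid = eap_grid(),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- generate_thetas(n, dist, bank$transform)
  resp <- simulate_responses(bank, theta)
  ids <- names(bank$items)
  records <- vector("list", n)
  items_administered <- vector("list", n)
  for (p in seq_len(n)) {
    full_resp <- structure(resp[p, ], names = ids)
    full <- full_length_score(full_resp, bank, grid)
    res <- administer_cat(bank, full_resp, control, grid)
    records[[p]] <- data.frame(
      respondent = p, theta_true = theta[p],
      full_theta = full$theta, full_se = full$se, full_score = full$score,
      cat_theta = res$final$theta, cat_se = res$final$se,
      cat_score = res$final$score, n_items = res$final$n_items,
      stop_reason = res$stop_reason, stringsAsFactors = FALSE)
    items_administered[[p]] <- res$state$administered
  }
  structure(list(records = do.call(rbind, records),
                 items_administered = items_administered,
                 responses = resp, bank = bank, control = control,
                 dist = dist, seed = seed),
            class = "cat_sim")
}

#' Item usage frequencies over a simulated cohort
#'
#' How often each bank item was administered by the CAT, as a count and a
#' percentage of respondents -- the item-reduction table of a CAT
#' evaluation. The most informative item at the population mean is
#' administered to every respondent.
#'
#' @param sim a `"cat_sim"`.
#' @return data.frame with columns `item_id`, `label`, `count`, `percent`,
#'   ordered as in the bank.
#' @export
usage_table <- function(sim) {
  ids <- names(sim$bank$items)
  counts <- table(factor(unlist(sim$items_administered), levels = ids))
  data.frame(item_id = ids,
             label = vapply(sim$bank$items, `[[`, "", "label"),
             count = as.integer(counts),
             percent = 100 * as.integer(counts) / nrow(sim$records),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.cat_sim <- function(x, ...) {
  r <- x$records
  cat(sprintf("CAT Monte Carlo simulation: %d respondents, %d-item bank\n",
              nrow(r), length(x$bank$items)))
  cat(sprintf("Items administered: median %g (IQR %g-%g, range %g-%g)\n",
              stats::median(r$n_items),
              stats::quantile(r$n_items, 0.25), stats::quantile(r$n_items, 0.75),
              min(r$n_items), max(r$n_items)))
  cat(sprintf("Median SEm at stop: %.3f (threshold %.2f)\n",
              stats::median(r$cat_se), x$control$se_threshold))
  invisible(x)
}

#' @export
summary.cat_sim <- function(object, ...) agreement_report(object)

#' Diagnostic plots for a simulated CAT evaluation
#'
#' `"distribution"` overlays the CAT and full-length score distributions;
#' `"regression"` plots CAT against full-length scores with the fitted
#' line; `"bland_altman"` plots paired differences against pair means with
#' the mean difference and 95% limits of agreement.
#'
#' @param x a `"cat_sim"`.
#' @param type which plot to draw.
#' @param ... passed to the underlying plot call.
#' @export
plot.cat_sim <- function(x, type = c("distribution", "regression",
                                     "bland_altman"), ...) {
  r <- x$records
  type <- match.arg(type)
  if (type == "distribution") {
    d1 <- stats::density(r$cat_score, from = 0, to = 100)
    d2 <- stats::density(r$full_score, from = 0, to = 100)
    graphics::plot(d2, col = "grey40", main = "Score distributions",
                   xlab = "Score (0-100)", ylim = c(0, max(d1$y, d2$y)), ...)
    graphics::lines(d1, col = "red")
    graphics::abline(v = c(mean(r$full_score), mean(r$cat_score)),
                     col = c("grey40", "red"), lty = 2)
    graphics::legend("topright", c("full-length", "CAT"),
                     col = c("grey40", "red"), lty = 1, bty = "n")
  } else if (type == "regression") {
    graphics::plot(r$full_score, r$cat_score, pch = 16, cex = 0.5,
                   xlab = "Full-length score", ylab = "CAT score",
                   main = "CAT vs full-length", ...)
    graphics::abline(stats::lm(cat_score ~ full_score, data = r), col = "red")
    graphics::abline(0, 1, lty = 2, col = "grey60")
  } else {
    diff <- r$cat_score - r$full_score
    avg <- (r$cat_score + r$full_score) / 2
    md <- mean(diff); s <- stats::sd(diff)
    graphics::plot(avg, diff, pch = 16, cex = 0.5,
                   xlab = "Mean of CAT and full-length score",
                   ylab = "CAT - full-length",
                   main = "Bland-Altman", ...)
    graphics::abline(h = md, col = "red")
    graphics::abline(h = md + c(-1.96, 1.96) * s, col = "red", lty = 2)
  }
  invisible(x)
}
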