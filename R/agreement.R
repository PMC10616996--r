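#' Agreement battery between CAT and full-length scores
#'
#' Computes the standard method-comparison battery on paired scores from a
#' simulated CAT evaluation (or any two paired score vectors): mean error,
#' mean absolute error and root mean square error of the CAT score against
#' the full-length score; Pearson's correlation; the intraclass
#' correlation coefficient ICC(A,1) (two-way mixed effects, absolute
#' agreement, single measurement); the explained variance R^2 and the
#' intercept/slope from regressing CAT scores on full-length scores; and a
#' Bland--Altman analysis with 95% limits of agreement
#' (mean difference +/- 1.96 SD of the differences). Differences are
#' oriented CAT minus full-length throughout.
#'
#' @param x a `"cat_sim"` object, or a numeric vector of CAT scores.
#' @param full numeric vector of full-length scores (when `x` is numeric).
#' @return An object of class `"agreement_report"`: a list of named
#'   metrics. If either arm has zero variance, the correlation-type
#'   metrics (`pearson_r`, `icc`, `r_squared`, `slope`) are `NA` with a
#'   `degenerate` flag set, never silently propagated NaN.
#' @examples
#' sim <- cat_simulate(pem_synthetic_bank(), n = 50, seed = 1)
#' agreement_report(sim)
#' @export
agreement_report <- function(x, full = NULL) {
  if (inherits(x, "cat_sim")) {
    cat_scores <- x$records$cat_score
    full_scores <- x$records$full_score
    n_items <- x$records$n_items
    sem <- x$records$cat_se
  } else {
    cat_scores <- as.numeric(x)
    full_scores <- as.numeric(full)
    n_items <- NULL
    sem <- NULL
  }
  if (length(cat_scores) < 3L || length(cat_scores) != length(full_scores))
    stop("agreement requires at least 3 paired scores")
  d <- cat_scores - full_scores
  degenerate <- stats::sd(cat_scores) == 0 || stats::sd(full_scores) == 0
  if (degenerate) {
    r <- r2 <- icc <- slope <- intercept <- NA_real_
  } else {
    r <- stats::cor(cat_scores, full_scores)
    fit <- stats::lm(cat_scores ~ full_scores)
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
    # exact agreement (exhaustive CAT) is a legitimate input; summary.lm
    # warns about the perfect fit, which is expected there
    r2 <- suppressWarnings(summary(fit)$r.squared)
    icc <- icc_a1(cat_scores, full_scores)
  }
  out <- list(
    n = length(d),
    mean_error = mean(d),
    mean_absolute_error = mean(abs(d)),
    rmse = sqrt(mean(d^2)),
    pearson_r = r,
    icc = icc,
    r_squared = r2,
    intercept = intercept,
    slope = slope,
    bland_altman = list(mean_difference = mean(d),
                        sd_difference = stats::sd(d),
                        loa_lower = mean(d) - 1.96 * stats::sd(d),
                        loa_upper = mean(d) + 1.96 * stats::sd(d)),
    cat_mean = mean(cat_scores), cat_sd = stats::sd(cat_scores),
    full_mean = mean(full_scores), full_sd = stats::sd(full_scores),
    degenerate = degenerate)
  if (!is.null(n_items)) {
    out$items <- list(median = stats::median(n_items),
                      iqr = unname(stats::quantile(n_items, c(0.25, 0.75))),
                      range = range(n_items))
    out$median_sem <- stats::median(sem)
  }
  structure(out, class = "agreement_report")
}

# ICC(A,1): two-way model, absolute agreement, single measurement, from the
# mean squares of the subjects x methods table (k = 2 methods here)
icc_a1 <- function(y1, y2) {
  n <- length(y1)
  k <- 2
  y <- cbind(y1, y2)
  grand <- mean(y)
  msr <- k * stats::var(rowMeans(y))                 # between-subjects
  msc <- n * sum((colMeans(y) - grand)^2) / (k - 1)  # between-methods
  sse <- sum((y - outer(rowMeans(y), rep(1, k)) -
                outer(rep(1, n), colMeans(y)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat(sprintf("Agreement between CAT and full-length scores (n = %d)\n", x$n))
  if (!is.null(x$items))
    cat(sprintf("  Items administered: median %g (IQR %g-%g, range %g-%g); median SEm %.2f\n",
                x$items$median, x$items$iqr[1], x$items$iqr[2],
                x$items$range[1], x$items$range[2], x$median_sem))
  cat(sprintf("  Scores: CAT mean %.1f (SD %.1f) vs full-length mean %.1f (SD %.1f)\n",
              x$cat_mean, x$cat_sd, x$full_mean, x$full_sd))
  cat(sprintf("  Mean error %.2f | MAE %.2f | RMSE %.2f\n",
              x$mean_error, x$mean_absolute_error, x$rmse))
  cat(sprintf("  Pearson r %.2f | ICC(A,1) %.2f | regression R^2 %.2f (intercept %.2f, slope %.2f)\n",
              x$pearson_r, x$icc, x$r_squared, x$intercept, x$slope))
  cat(sprintf("  Bland-Altman: mean difference %.2f, 95%% LoA [%.2f, %.2f]\n",
              x$bland_altman$mean_difference, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper))
  invisible(x)
}
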