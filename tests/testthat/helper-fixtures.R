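# Shared fixtures and independent oracles for the test suite.

# a tiny hand-specified bank: 3 items, mixed category counts
toy_bank <- function() {
  item_bank(discrimination = c(1.5, 2.0, 1.0),
            thresholds = list(c(-1, 0, 1), c(-0.5, 0.5), 0),
            ids = c("A", "B", "C"))
}

# dense-grid EAP oracle: posterior moments by trapezoid integration on a
# 100001-point grid, computed directly from first principles
oracle_eap <- function(responses, bank, n = 100001, range = c(-6, 6)) {
  th <- seq(range[1], range[2], length.out = n)
  logpost <- dnorm(th, log = TRUE)
  for (id in names(responses)) {
    item <- bank$items[[id]]
    p <- vapply(th, function(t) {
      b <- c(1, plogis(item$discrimination * (t - item$thresholds)), 0)
      b[responses[[id]]] - b[responses[[id]] + 1L]
    }, numeric(1))
    logpost <- logpost + log(pmax(p, 1e-300))
  }
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  m <- sum(w * th)
  list(theta = m, se = sqrt(sum(w * (th - m)^2)))
}

# dense-grid marginal log-likelihood oracle (trapezoid rule)
oracle_marginal_loglik <- function(data, bank, n = 10001, range = c(-6, 6)) {
  th <- seq(range[1], range[2], length.out = n)
  h <- diff(range) / (n - 1)
  total <- 0
  for (p in seq_len(nrow(data))) {
    f <- dnorm(th)
    for (j in seq_len(ncol(data))) {
      x <- data[p, j]
      if (is.na(x)) next
      f <- f * category_probabilities(bank$items[[colnames(data)[j]]], th)[, x]
    }
    trap <- h * (sum(f) - (f[1] + f[n]) / 2)
    total <- total + log(trap)
  }
  total
}

# parameter-recovery fit is expensive; compute once and reuse across files
.fit_cache <- new.env(parent = emptyenv())
recovery_fixture <- function() {
  if (is.null(.fit_cache$fit)) {
    bank <- make_fixture_bank(seed = 7)
    fx <- make_fixture_responses(bank, 1000, seed = 11)
    fit <- suppressWarnings(grm(fx$responses))
    .fit_cache$bank <- bank
    .fit_cache$fit <- fit
  }
  list(truth = .fit_cache$bank, fit = .fit_cache$fit)
}
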