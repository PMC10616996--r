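test_that("latent-trait generators honour their distribution specs", {
  set.seed(50)
  th <- generate_thetas(1e5, theta_dist("normal"))
  expect_lt(abs(mean(th)), 0.02)
  expect_lt(abs(sd(th) - 1), 0.02)
  # score-scale normal back-transforms through the bank transform
  th2 <- generate_thetas(1e5, theta_dist("score_normal", 43.9, 18.7),
                         scale_transform(12.5, 50))
  expect_equal(mean(th2), (43.9 - 50) / 12.5, tolerance = 0.02)
  expect_equal(sd(th2), 18.7 / 12.5, tolerance = 0.02)
  expect_identical(generate_thetas(7, theta_dist("empirical", values = 1.3)),
                   rep(1.3, 7))
  expect_error(theta_dist("empirical"), "non-empty")
})

test_that("simulated responses are seeded draws from the GRM probabilities", {
  bank <- pem_synthetic_bank()
  set.seed(1); r1 <- simulate_responses(bank, rnorm(20))
  set.seed(1); r2 <- simulate_responses(bank, rnorm(20))
  expect_identical(r1, r2)
  # far above every threshold the top category dominates
  p_top <- vapply(bank$items, function(it)
    category_probabilities(it, 8)[, it$n_categories], numeric(1))
  expect_true(all(p_top > 0.99))
  set.seed(2)
  high <- simulate_responses(bank, rep(8, 200))
  expect_gt(mean(high == 7L), 0.98)
  # empirical frequencies match the closed form at a fixed trait
  one <- item_bank(bank$items$Q4$discrimination,
                   list(bank$items$Q4$thresholds), ids = "Q4")
  set.seed(3)
  draws <- simulate_responses(one, rep(0.5, 1e5))
  freq <- tabulate(draws, 7) / 1e5
  expect_equal(freq, drop(category_probabilities(one$items$Q4, 0.5)),
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("the Monte Carlo run is reproducible and internally consistent", {
  bank <- pem_synthetic_bank()
  sim1 <- cat_simulate(bank, n = 30, seed = 123)
  sim2 <- cat_simulate(bank, n = 30, seed = 123)
  expect_identical(sim1$records, sim2$records)
  # usage conservation: counts sum to total items administered
  ut <- usage_table(sim1)
  expect_equal(sum(ut$count), sum(sim1$records$n_items))
  expect_true(all(ut$count <= 30))
  # the information argmax at the prior mean opens every session
  first <- vapply(sim1$items_administered, `[`, "", 1)
  expect_true(all(first == first[1]))
  expect_equal(ut$count[ut$item_id == first[1]], 30L)
})

test_that("agreement metrics reproduce closed forms on identity and shifted scores", {
  x <- c(31, 47, 55, 62, 78)
  id <- agreement_report(x, x)
  expect_equal(id$mean_error, 0)
  expect_equal(id$mean_absolute_error, 0)
  expect_equal(id$rmse, 0)
  expect_equal(id$pearson_r, 1)
  expect_equal(id$icc, 1)
  expect_equal(id$r_squared, 1)
  expect_equal(id$bland_altman$loa_lower, 0)
  expect_equal(id$bland_altman$loa_upper, 0)
  sh <- agreement_report(x + 2, x)
  expect_equal(sh$mean_error, 2)
  expect_equal(sh$mean_absolute_error, 2)
  expect_equal(sh$rmse, 2)
  expect_equal(sh$bland_altman$sd_difference, 0)
  expect_equal(sh$bland_altman$loa_lower, 2)
  expect_equal(sh$bland_altman$loa_upper, 2)
  expect_equal(sh$pearson_r, 1)
  expect_equal(sh$slope, 1)
  expect_equal(sh$intercept, 2)
})

test_that("agreement metrics match formula-by-formula recomputation at n = 5", {
  cat_s <- c(40.2, 55.1, 48.9, 61.3, 35.7)
  full_s <- c(42.0, 54.0, 50.5, 60.0, 33.9)
  rep <- agreement_report(cat_s, full_s)
  d <- cat_s - full_s
  expect_equal(rep$mean_error, mean(d))
  expect_equal(rep$mean_absolute_error, mean(abs(d)))
  expect_equal(rep$rmse, sqrt(mean(d^2)))
  expect_equal(rep$pearson_r, cor(cat_s, full_s))
  fit <- lm(cat_s ~ full_s)
  expect_equal(rep$r_squared, summary(fit)$r.squared)
  expect_equal(rep$intercept, unname(coef(fit)[1]))
  expect_equal(rep$slope, unname(coef(fit)[2]))
  expect_equal(rep$bland_altman$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(rep$bland_altman$loa_upper, mean(d) + 1.96 * sd(d))
  # ICC(A,1) cross-checked through the two-way ANOVA mean squares
  long <- data.frame(y = c(cat_s, full_s),
                     subject = factor(rep(1:5, 2)),
                     method = factor(rep(1:2, each = 5)))
  ms <- anova(lm(y ~ subject + method, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse + 2 / 5 * (msc - mse))
  expect_equal(rep$icc, icc_oracle, tolerance = 1e-12)
  # calibration-free bounds
  expect_gte(rep$mean_absolute_error, abs(rep$mean_error))
  expect_gte(rep$rmse, abs(rep$mean_error))
})

test_that("degenerate zero-variance arms yield flagged NA metrics, not NaN", {
  rep <- agreement_report(rep(50, 5), rep(50, 5))
  expect_true(rep$degenerate)
  expect_true(is.na(rep$pearson_r) && is.na(rep$icc) && is.na(rep$r_squared))
  expect_equal(rep$rmse, 0)
})

test_that("agreement converges to identity as the precision threshold vanishes", {
  bank <- pem_synthetic_bank()
  sim <- cat_simulate(bank, n = 200, control = cat_control(se_threshold = 1e-6),
                      seed = 6)
  expect_true(all(sim$records$stop_reason == "bank_exhausted"))
  expect_true(all(sim$records$n_items == 10L))
  rep <- agreement_report(sim)
  expect_equal(rep$mean_error, 0, tolerance = 1e-10)
  expect_equal(rep$mean_absolute_error, 0, tolerance = 1e-10)
  expect_equal(rep$rmse, 0, tolerance = 1e-10)
  expect_equal(rep$pearson_r, 1, tolerance = 1e-10)
  expect_equal(rep$icc, 1, tolerance = 1e-10)
  expect_equal(rep$r_squared, 1, tolerance = 1e-10)
  ut <- usage_table(sim)
  expect_true(all(ut$percent == 100))
})
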