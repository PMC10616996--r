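test_that("item bank constructor enforces GRM parameter invariants", {
  expect_error(item_bank(-1, list(0)), "positive")
  expect_error(item_bank(1, list(c(1, -1))), "strictly increasing")
  expect_error(item_bank(c(1, 1), list(0, 0), ids = c("A", "A")), "unique")
  bank <- toy_bank()
  expect_equal(length(bank), 3L)
  expect_equal(bank$items$A$n_categories, 4L)
})

test_that("boundary probabilities follow the logistic closed form", {
  it1 <- item_bank(1, list(0))$items[[1]]
  expect_equal(drop(boundary_probabilities(it1, 0)), 0.5, ignore_attr = TRUE)
  it2 <- item_bank(2, list(c(-1, 1)))$items[[1]]
  expect_equal(drop(boundary_probabilities(it2, 0)),
               c(plogis(2), plogis(-2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # logistic tail: all boundaries vanish far below the thresholds
  expect_true(all(boundary_probabilities(it2, -40) < 1e-12))
})

test_that("category probabilities are boundary differences summing to one", {
  it1 <- item_bank(1, list(0))$items[[1]]
  expect_equal(unname(drop(category_probabilities(it1, 0))), c(0.5, 0.5))
  it2 <- item_bank(2, list(c(-1, 1)))$items[[1]]
  p <- drop(category_probabilities(it2, 0))
  expect_equal(p, c(1 - plogis(2), plogis(2) - plogis(-2), plogis(-2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("normalization and boundary monotonicity hold across random items", {
  set.seed(101)
  for (rep in 1:25) {
    K <- sample(2:7, 1)
    it <- item_bank(runif(1, 0.3, 4),
                    list(sort(runif(K - 1, -3, 3)) + seq_len(K - 1) * 1e-3))$items[[1]]
    theta <- seq(-6, 6, length.out = 41)
    P <- category_probabilities(it, theta)
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, length(theta)), tolerance = 1e-10)
    B <- boundary_probabilities(it, theta)
    # strictly increasing in theta, strictly decreasing in boundary index
    expect_true(all(apply(B, 2, diff) > 0))
    if (ncol(B) > 1) expect_true(all(t(apply(B, 1, diff)) < 0))
  }
})

test_that("item information reduces to a^2 P (1 - P) for dichotomous items", {
  expect_equal(item_information(item_bank(1, list(0))$items[[1]], 0), 0.25)
  expect_equal(item_information(item_bank(2, list(0))$items[[1]], 0), 1.0)
  set.seed(5)
  for (rep in 1:10) {
    a <- runif(1, 0.3, 3); b <- runif(1, -2, 2)
    it <- item_bank(a, list(b))$items[[1]]
    theta <- seq(-4, 4, length.out = 17)
    P <- drop(boundary_probabilities(it, theta))
    expect_equal(item_information(it, theta), a^2 * P * (1 - P),
                 tolerance = 1e-8)
  }
})

test_that("information is nonnegative and additive over items", {
  bank <- make_fixture_bank(seed = 3)
  theta <- seq(-5, 5, length.out = 21)
  for (it in bank$items) expect_true(all(item_information(it, theta) >= 0))
  # brute-force summation oracle
  manual <- Reduce(`+`, lapply(bank$items, item_information, theta = theta))
  expect_identical(test_information(bank, theta), manual)
  one <- names(bank$items)[4]
  expect_identical(test_information(bank, theta, items = one),
                   item_information(bank$items[[one]], theta))
  twice <- item_bank(c(1.2, 1.2), list(c(-1, 1), c(-1, 1)))
  expect_equal(test_information(twice, 0.3),
               2 * item_information(twice$items[[1]], 0.3))
  expect_error(test_information(bank, 0, items = character(0)), "at least one")
})

test_that("response log-likelihood matches a term-by-term product oracle", {
  bank <- toy_bank()
  expect_identical(response_loglik(integer(0), bank, c(-1, 0, 1)), c(0, 0, 0))
  it <- item_bank(1, list(0), ids = "D")
  expect_equal(response_loglik(c(D = 2L), it, 0), log(0.5))
  resp <- c(A = 3L, B = 1L, C = 2L)
  theta <- c(-2, 0, 1.5)
  manual <- log(category_probabilities(bank$items$A, theta)[, 3]) +
    log(category_probabilities(bank$items$B, theta)[, 1]) +
    log(category_probabilities(bank$items$C, theta)[, 2])
  expect_equal(response_loglik(resp, bank, theta), manual, tolerance = 1e-12)
  expect_true(all(response_loglik(resp, bank, seq(-6, 6, 0.5)) <= 0))
  expect_error(response_loglik(c(Z = 1L), bank, 0), "unknown item")
  expect_error(response_loglik(c(A = 5L), bank, 0), "outside")
})
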