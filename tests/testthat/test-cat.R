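test_that("a fresh CAT session starts at the population average", {
  bank <- pem_synthetic_bank()
  state <- initialize_cat(bank)
  expect_equal(state$current$theta, 0, tolerance = 1e-10)
  expect_equal(state$current$se, 1, tolerance = 1e-4)
  expect_equal(state$current$score, 50)
  expect_equal(nrow(state$trace), 0L)
  expect_length(state$administered, 0L)
})

test_that("item selection maximizes information with a deterministic tie-break", {
  bank <- make_fixture_bank(seed = 13)
  state <- initialize_cat(bank)
  # exhaustive-scan oracle over all unadministered items
  info <- vapply(bank$items, item_information, numeric(1),
                 theta = state$current$theta)
  expect_identical(select_next_item(state, bank), names(which.max(info)))
  # singleton case
  state2 <- state
  state2$administered <- names(bank$items)[-4]
  expect_identical(select_next_item(state2, bank), names(bank$items)[4])
  # two identical items: lowest bank index wins
  twin <- item_bank(c(2, 2), list(c(-1, 1), c(-1, 1)), ids = c("T1", "T2"))
  expect_identical(select_next_item(initialize_cat(twin), twin), "T1")
  state3 <- state
  state3$administered <- names(bank$items)
  expect_error(select_next_item(state3, bank), "all items")
})

test_that("recording a response re-estimates exactly as the scoring module", {
  bank <- pem_synthetic_bank()
  state <- initialize_cat(bank)
  first <- select_next_item(state, bank)
  state <- record_response(state, first, 6L, bank)
  expect_equal(state$current$n_items, 1L)
  expect_equal(nrow(state$trace), 1L)
  direct <- eap_estimate(structure(6L, names = first), bank)
  expect_identical(state$current, direct)
  # a top-category response moves the estimate upward
  expect_gt(state$current$theta, 0)
  prev <- state$current$theta
  nxt <- select_next_item(state, bank)
  state <- record_response(state, nxt, 7L, bank)
  expect_gt(state$current$theta, prev)
  expect_error(record_response(state, first, 3L, bank), "already")
  expect_error(record_response(state, "Q2", 9L, bank), "outside")
})

test_that("the stopping rule uses a strict SEm threshold", {
  bank <- pem_synthetic_bank()
  fake <- function(se, n) {
    structure(list(administered = names(bank$items)[seq_len(n)],
                   current = list(se = se)), class = "cat_state")
  }
  expect_identical(should_stop(fake(0.29, 1), bank),
                   list(stop = TRUE, reason = "precision_met"))
  # SEm exactly at the threshold does not stop: the inequality is strict
  verdict <- should_stop(fake(0.30, 1), bank)
  expect_false(verdict$stop)
  expect_identical(should_stop(fake(0.5, 10), bank),
                   list(stop = TRUE, reason = "bank_exhausted"))
  expect_identical(
    should_stop(fake(0.5, 3), bank, cat_control(max_items = 3)),
    list(stop = TRUE, reason = "max_items"))
  # min_items floor delays a precision stop
  expect_false(should_stop(fake(0.1, 1), bank, cat_control(min_items = 2))$stop)
})

test_that("administration replays the select-ask-record loop deterministically", {
  bank <- pem_synthetic_bank()
  set.seed(77)
  resp <- structure(sample(1:7, 10, TRUE), names = names(bank$items))
  res <- administer_cat(bank, resp)
  # step-by-step replay oracle
  state <- initialize_cat(bank)
  for (step in seq_len(nrow(res$state$trace))) {
    expected <- select_next_item(state, bank)
    expect_identical(res$state$trace$item_id[step], expected)
    state <- record_response(state, expected, resp[[expected]], bank)
  }
  expect_identical(res$final, state$current)
  # byte-identical replay
  res2 <- administer_cat(bank, resp)
  expect_identical(res$state$trace, res2$state$trace)
  if (res$stop_reason == "precision_met")
    expect_lt(res$final$se, 0.3)
})

test_that("an unreachable threshold administers every item and reproduces the full-length score", {
  bank <- pem_synthetic_bank()
  set.seed(88)
  for (rep in 1:3) {
    resp <- structure(sample(1:7, 10, TRUE), names = names(bank$items))
    res <- administer_cat(bank, resp, cat_control(se_threshold = 0))
    expect_identical(res$stop_reason, "bank_exhausted")
    expect_equal(res$final$n_items, 10L)
    full <- full_length_score(resp, bank)
    expect_equal(res$final$theta, full$theta, tolerance = 1e-10)
    expect_equal(res$final$se, full$se, tolerance = 1e-10)
  }
})

test_that("a response provider callback drives the test and is validated", {
  bank <- pem_synthetic_bank()
  asked <- character(0)
  provider <- function(item_id) {
    asked <<- c(asked, item_id)
    4L
  }
  res <- administer_cat(bank, provider)
  expect_identical(asked, res$state$administered)
  expect_error(administer_cat(bank, function(item_id) 99L), "outside")
})
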