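#' CAT administration settings
#'
#' @param se_threshold precision threshold on the logit scale: the test
#'   stops once the posterior SD (SEm) is strictly below this value.
#'   Default 0.3, the PROMIS-style precision convention.
#' @param min_items minimum number of items to administer before the
#'   precision rule may stop the test.
#' @param max_items maximum number of items (default: the whole bank).
#' @param selection item-selection rule; `"max_info"` administers the
#'   unasked item with the largest Fisher information at the current
#'   point estimate.
#' @param tie_break among equally informative items, `"first"` picks the
#'   lowest bank index.
#' @return An object of class `"cat_control"`.
#' @export
cat_control <- function(se_threshold = 0.3, min_items = 1L, max_items = NULL,
                        selection = c("max_info"), tie_break = c("first")) {
  if (!is.finite(se_threshold) || se_threshold < 0)
    stop("`se_threshold` must be nonnegative")
  if (min_items < 1L) stop("`min_items` must be at least 1")
  if (!is.null(max_items) && max_items < min_items)
    stop("`max_items` must be >= `min_items`")
  structure(list(se_threshold = se_threshold, min_items = as.integer(min_items),
                 max_items = if (!is.null(max_items)) as.integer(max_items),
                 selection = match.arg(selection),
                 tie_break = match.arg(tie_break)),
            class = "cat_control")
}

#' Start a CAT session
#'
#' Creates the empty session state: no items administered, current estimate
#' equal to the prior-only EAP (population mean, prior SD), empty trace.
#'
#' @param bank an [item_bank()].
#' @param control a [cat_control()].
#' @param grid quadrature from [eap_grid()].
#' @return An object of class `"cat_state"` with fields `administered`,
#'   `responses`, `current` and `trace` (one row per administered item).
#' @export
initialize_cat <- function(bank, control = cat_control(), grid = eap_grid()) {
  responses <- structure(integer(0), names = character(0))
  structure(list(administered = character(0), responses = responses,
                 current = eap_estimate(responses, bank, grid),
                 trace = empty_trace()),
            class = "cat_state")
}

empty_trace <- function() {
  data.frame(step = integer(0), item_id = character(0), response = integer(0),
             theta = numeric(0), se = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Select the next CAT item
#'
#' Returns the id of the unadministered item with maximal Fisher
#' information at the current latent-trait estimate; ties go to the lowest
#' bank index, so selection is fully deterministic.
#'
#' @param state a `"cat_state"`.
#' @inheritParams initialize_cat
#' @export
select_next_item <- function(state, bank, control = cat_control()) {
  remaining <- setdiff(names(bank$items), state$administered)
  if (length(remaining) == 0L) stop("all items have been administered")
  info <- vapply(remaining, function(id)
    item_information(bank_item(bank, id), state$current$theta), numeric(1))
  remaining[which.max(info)]  # which.max: first maximum = lowest bank index
}

#' Record a response and re-estimate
#'
#' Appends one administered item and its response to the session, then
#' recomputes the EAP estimate from all responses collected so far. The
#' trace row holds the post-response estimate, giving the score trajectory
#' of the session.
#'
#' @param state a `"cat_state"`.
#' @param item_id the item just administered.
#' @param category 1-based response category.
#' @inheritParams initialize_cat
#' @export
record_response <- function(state, item_id, category, bank, grid = eap_grid()) {
  if (item_id %in% state$administered)
    stop(sprintf("item '%s' has already been administered", item_id))
  item <- bank_item(bank, item_id)
  if (is.na(category) || category < 1L || category > item$n_categories)
    stop(sprintf("item '%s': category %s outside 1..%d", item_id,
                 format(category), item$n_categories))
  responses <- c(state$responses, structure(as.integer(category), names = item_id))
  current <- eap_estimate(responses, bank, grid)
  step <- data.frame(step = length(responses), item_id = item_id,
                     response = as.integer(category), theta = current$theta,
                     se = current$se, score = current$score,
                     stringsAsFactors = FALSE)
  structure(list(administered = c(state$administered, item_id),
                 responses = responses, current = current,
                 trace = rbind(state$trace, step)),
            class = "cat_state")
}

#' CAT stopping rule
#'
#' The test stops with reason `"precision_met"` once at least `min_items`
#' items have been administered and the SEm is strictly below
#' `se_threshold`; with `"bank_exhausted"` when no items remain; with
#' `"max_items"` when the item cap is reached.
#'
#' @param state a `"cat_state"`.
#' @inheritParams initialize_cat
#' @return A list `list(stop = logical, reason = character or NULL)`.
#' @export
should_stop <- function(state, bank, control = cat_control()) {
  n <- length(state$administered)
  if (n >= control$min_items && state$current$se < control$se_threshold)
    return(list(stop = TRUE, reason = "precision_met"))
  if (n >= length(bank$items))
    return(list(stop = TRUE, reason = "bank_exhausted"))
  if (!is.null(control$max_items) && n >= control$max_items)
    return(list(stop = TRUE, reason = "max_items"))
  list(stop = FALSE, reason = NULL)
}

#' Administer a computerized adaptive test
#'
#' Runs the full adaptive loop: select the most informative item at the
#' current estimate, obtain the response, re-estimate, and stop once the
#' precision threshold is met (or the bank/item cap is exhausted).
#'
#' `responses` may be either a complete (or sufficient) named response
#' vector -- the usual case when replaying recorded or simulated response
#' sets -- or a function `function(item_id) -> category` that produces
#' responses on demand (e.g. a console prompt for live administration).
#'
#' @param bank an [item_bank()].
#' @param responses named integer vector or response-provider function.
#' @param control a [cat_control()].
#' @param grid quadrature from [eap_grid()].
#' @return An object of class `"cat_result"`: list with `final` (the
#'   closing `"theta_estimate"`), `state` (full session including the
#'   per-step trace) and `stop_reason`.
#' @examples
#' bank <- pem_synthetic_bank()
#' full <- structure(rep(4L, 10), names = names(bank$items))
#' res <- administer_cat(bank, full)
#' res
#' @export
administer_cat <- function(bank, responses, control = cat_control(),
                           grid = eap_grid()) {
  provider <- if (is.function(responses)) {
    responses
  } else {
    validate_responses(responses, bank)
    function(item_id) {
      if (!item_id %in% names(responses))
        stop(sprintf("no response available for selected item '%s'", item_id))
      responses[[item_id]]
    }
  }
  state <- initialize_cat(bank, control, grid)
  initial <- state$current
  repeat {
    verdict <- should_stop(state, bank, control)
    if (verdict$stop) {
      return(structure(list(final = state$current, initial = initial,
                            state = state, stop_reason = verdict$reason,
                            bank_size = length(bank$items)),
                       class = "cat_result"))
    }
    item_id <- select_next_item(state, bank, control)
    state <- record_response(state, item_id, provider(item_id), bank, grid)
  }
}

#' @export
print.cat_result <- function(x, ...) {
  cat(sprintf("Adaptive test: %d of %d candidate items administered (stop: %s)\n",
              x$final$n_items, x$bank_size, x$stop_reason))
  print(x$final)
  if (nrow(x$state$trace) > 0) {
    cat("Trace:\n")
    print(x$state$trace, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Plot a CAT score trajectory
#'
#' Shows the running 0--100 score after each administered item, with a
#' 95% confidence band (1.96 SE) -- the familiar CAT trace starting at the
#' population average before any item is answered.
#'
#' @param x a `"cat_result"`.
#' @param reference optional full-length score drawn as a horizontal line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cat_result <- function(x, reference = NULL, ...) {
  tr <- x$state$trace
  slope <- x$initial$score_se / x$initial$se
  steps <- c(0, tr$step)
  score <- c(x$initial$score, tr$score)
  se <- c(x$initial$se, tr$se)
  graphics::plot(steps, score, type = "b", pch = 16, ylim = c(0, 100),
                 xlab = "Items administered", ylab = "Score (0-100)",
                 main = "CAT score trace", xaxt = "n", ...)
  graphics::axis(1, at = steps)
  band <- 1.96 * se * slope
  graphics::arrows(steps, score - band, steps, score + band,
                   angle = 90, code = 3, length = 0.04, col = "grey40")
  if (!is.null(reference))
    graphics::abline(h = reference, col = "red", lty = 1)
  invisible(x)
}
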