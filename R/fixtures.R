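#' Generate a synthetic item bank
#'
#' Creates a reproducible random GRM item bank shaped like a short ordinal
#' patient-reported outcome instrument: by default 10 items with 7 response
#' categories, discriminations varying across items (so adaptive item
#' ordering is non-trivial) and evenly spread thresholds with per-item
#' location shifts and jitter.
#'
#' @param n_items number of items.
#' @param n_categories response categories per item (`K`), `>= 2`.
#' @param discrimination_range range from which item slopes are drawn
#'   (log-uniform).
#' @param threshold_range interval over which each item's thresholds are
#'   spread before jitter.
#' @param seed optional integer seed.
#' @param transform a [scale_transform()] for the bank.
#' @return An [item_bank()].
#' @export
make_fixture_bank <- function(n_items = 10, n_categories = 7,
                              discrimination_range = c(0.9, 3),
                              threshold_range = c(-2.5, 2.5),
                              seed = NULL,
                              transform = scale_transform()) {
  if (!is.null(seed)) set.seed(seed)
  if (n_categories < 2) stop("`n_categories` must be at least 2")
  a <- exp(stats::runif(n_items, log(discrimination_range[1]),
                        log(discrimination_range[2])))
  thresholds <- lapply(seq_len(n_items), function(i) {
    base <- seq(threshold_range[1], threshold_range[2],
                length.out = n_categories + 1L)[2:n_categories]
    shift <- stats::runif(1, -0.5, 0.5)
    jitter <- stats::rnorm(n_categories - 1L, sd = 0.08)
    sort_strict(base + shift + jitter)
  })
  item_bank(a, thresholds, transform = transform,
            metadata = list(instrument = "synthetic fixture", version = "1"))
}

# sort and force strictly increasing (minimum gap keeps invariants under jitter)
sort_strict <- function(x, gap = 1e-3) {
  x <- sort(x)
  for (i in seq_along(x)[-1]) if (x[i] - x[i - 1] < gap) x[i] <- x[i - 1] + gap
  x
}

#' Generate synthetic ordinal response data
#'
#' Draws a complete person by item response matrix from a bank at latent
#' traits sampled from a [theta_dist()], optionally punching random holes
#' to emulate incomplete registry data.
#'
#' @param bank an [item_bank()].
#' @param n number of persons.
#' @param dist a [theta_dist()] for the generating traits.
#' @param missing_rate proportion of cells set to `NA` at random.
#' @param seed optional integer seed.
#' @return List with `responses` (integer matrix with item-id columns,
#'   person ids as rownames) and `theta` (the generating traits).
#' @export
make_fixture_responses <- function(bank, n, dist = theta_dist(),
                                   missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- generate_thetas(n, dist, bank$transform)
  resp <- simulate_responses(bank, theta)
  if (missing_rate > 0) {
    holes <- which(stats::runif(length(resp)) < missing_rate)
    resp[holes] <- NA_integer_
  }
  rownames(resp) <- paste0("P", seq_len(n))
  list(responses = resp, theta = theta)
}

#' Synthetic stand-in bank for the 10-item Patient Evaluation Measure
#'
#' A fixed, fully synthetic GRM item bank shaped like the original 10-item
#' Patient Evaluation Measure (PEM): ten 7-category bipolar-adjective items
#' about hand function. The item wordings are the PEM's; the parameters are
#' NOT the published calibration -- they were constructed so that the
#' bank's informativeness profile matches the behaviour reported for the
#' calibrated instrument in cubital tunnel syndrome patients: the everyday
#' activities item (Q7) is by far the most informative, followed by the
#' work item (Q8), together precise enough that two items usually push the
#' SEm below 0.3; the appearance items (Q9, Q10) carry little information.
#' Threshold locations centre slightly below the trait mean of a surgical
#' cohort.
#'
#' Use it to exercise the CAT engine and the Monte Carlo evaluation when
#' the published parameters are not at hand; do not use it to score real
#' PEM responses.
#'
#' @return An [item_bank()] with the default 0--100 transform
#'   (`score = 12.5 * theta + 50`).
#' @export
pem_synthetic_bank <- function() {
  labels <- c(
    Q1  = "Feeling in the hand is now",
    Q2  = "Pain when the hand is cold/damp",
    Q3  = "Pain in the hand most of the time",
    Q4  = "Ability to use the hand for fiddly things",
    Q5  = "General movement of the hand",
    Q6  = "Hand grip",
    Q7  = "Hand usage for everyday activities",
    Q8  = "Hand usage for work",
    Q9  = "Feeling when looking at hand appearance",
    Q10 = "Feeling when thinking about the hand")
  a <- c(Q1 = 2.3, Q2 = 1.8, Q3 = 2.0, Q4 = 2.9, Q5 = 2.1,
         Q6 = 2.6, Q7 = 5.2, Q8 = 4.9, Q9 = 1.2, Q10 = 1.1)
  centre <- c(Q1 = -0.75, Q2 = 0.00, Q3 = -0.20, Q4 = -0.35, Q5 = -0.40,
              Q6 = -0.60, Q7 = -0.50, Q8 = -0.45, Q9 = -0.10, Q10 = 0.10)
  spacing <- c(Q1 = 0.75, Q2 = 0.80, Q3 = 0.78, Q4 = 0.70, Q5 = 0.74,
               Q6 = 0.72, Q7 = 0.60, Q8 = 0.62, Q9 = 0.85, Q10 = 0.88)
  thresholds <- lapply(names(labels), function(id)
    centre[[id]] + spacing[[id]] * (seq_len(6) - 3.5))
  item_bank(unname(a), thresholds, ids = names(labels),
            labels = unname(labels),
            transform = scale_transform(slope = 12.5, offset = 50),
            metadata = list(
              instrument = "Patient Evaluation Measure (10-item), synthetic stand-in",
              version = "synthetic-1",
              note = paste("Synthetic parameters emulating the calibrated",
                           "instrument's informativeness profile; not the",
                           "published calibration.")))
}
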