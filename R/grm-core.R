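#' Construct an item bank
#'
#' An item bank holds the graded response model (GRM) parameterization of
#' every candidate item of an instrument: a positive discrimination (logit
#' slope) `a` and strictly increasing category boundary locations
#' `b_1 < ... < b_{K-1}` per item, together with the affine transform used to
#' report latent-trait scores on the 0--100 scale.
#'
#' The GRM is parameterized in the pure logistic metric (scaling constant
#' D = 1): the probability of responding in category `k` or above is
#' `P(X >= k | theta) = plogis(a * (theta - b_{k-1}))` for `k = 2..K`.
#'
#' @param discrimination numeric vector of item slopes, all `> 0`.
#' @param thresholds list of numeric vectors; element `i` holds the
#'   `K_i - 1` strictly increasing boundary locations of item `i`.
#' @param ids character vector of unique item identifiers. Defaults to
#'   `"Q1" ... "Qn"`.
#' @param labels optional character vector of item wordings.
#' @param transform a [scale_transform()] mapping logits to reported scores.
#' @param metadata named list of provenance strings (instrument, version...).
#'
#' @return An object of class `"item_bank"`: a list with elements `items`
#'   (one list per item with `id`, `label`, `n_categories`, `discrimination`,
#'   `thresholds`), `transform` and `metadata`.
#' @seealso [category_probabilities()], [item_information()], [read_item_bank()]
#' @examples
#' bank <- item_bank(discrimination = c(2, 1.5),
#'                   thresholds = list(c(-1, 0, 1), c(-0.5, 0.5)))
#' bank
#' @export
item_bank <- function(discrimination, thresholds, ids = NULL, labels = NULL,
                      transform = scale_transform(), metadata = list()) {
  if (!is.list(thresholds)) thresholds <- list(thresholds)
  n <- length(discrimination)
  if (length(thresholds) != n)
    stop("`discrimination` and `thresholds` must have one entry per item")
  if (n == 0L) stop("an item bank must contain at least one item")
  if (is.null(ids)) ids <- paste0("Q", seq_len(n))
  if (anyDuplicated(ids)) stop("item ids must be unique")
  if (is.null(labels)) labels <- ids
  items <- vector("list", n)
  for (i in seq_len(n)) {
    items[[i]] <- new_item(ids[i], labels[i], discrimination[i],
                           as.numeric(thresholds[[i]]))
  }
  names(items) <- ids
  structure(list(items = items, transform = transform, metadata = metadata),
            class = "item_bank")
}

new_item <- function(id, label, discrimination, thresholds) {
  item <- list(id = as.character(id), label = as.character(label),
               n_categories = length(thresholds) + 1L,
               discrimination = as.numeric(discrimination),
               thresholds = as.numeric(thresholds))
  validate_item(item)
  item
}

validate_item <- function(item) {
  if (!is.finite(item$discrimination) || item$discrimination <= 0)
    stop(sprintf("item '%s': discrimination must be a positive number", item$id))
  b <- item$thresholds
  if (length(b) < 1L || anyNA(b) || any(!is.finite(b)))
    stop(sprintf("item '%s': thresholds must be finite and non-empty", item$id))
  if (any(diff(b) <= 0))
    stop(sprintf("item '%s': thresholds must be strictly increasing", item$id))
  if (item$n_categories != length(b) + 1L)
    stop(sprintf("item '%s': n_categories must equal length(thresholds) + 1", item$id))
  invisible(item)
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Item bank: %d items, %s categories\n", length(x$items),
              paste(unique(vapply(x$items, `[[`, 1L, "n_categories")),
                    collapse = "/")))
  if (!is.null(x$metadata$instrument))
    cat("Instrument:", x$metadata$instrument, "\n")
  cat(sprintf("Score transform: score = %.4g * theta + %.4g, clipped to [0, 100]\n",
              x$transform$slope, x$transform$offset))
  print(coef(x), digits = 3)
  invisible(x)
}

#' @export
coef.item_bank <- function(object, ...) {
  items <- object$items
  kmax <- max(vapply(items, `[[`, 1L, "n_categories"))
  out <- matrix(NA_real_, length(items), kmax,
                dimnames = list(names(items),
                                c("a", paste0("b", seq_len(kmax - 1L)))))
  for (i in seq_along(items)) {
    out[i, 1L] <- items[[i]]$discrimination
    out[i, seq_along(items[[i]]$thresholds) + 1L] <- items[[i]]$thresholds
  }
  out
}

#' @export
length.item_bank <- function(x) length(x$items)

bank_item <- function(bank, item_id) {
  item <- bank$items[[item_id]]
  if (is.null(item)) stop(sprintf("unknown item '%s'", item_id))
  item
}

#' GRM boundary probabilities
#'
#' Probability of responding in category `k + 1` or above, for each of the
#' item's `K - 1` boundaries, evaluated at one or more latent-trait values.
#'
#' @param item a single item from an [item_bank()] (or a list with
#'   `discrimination` and `thresholds`).
#' @param theta numeric vector of latent-trait values (logits).
#' @return A `length(theta) x (K-1)` matrix of boundary probabilities,
#'   strictly decreasing along each row.
#' @examples
#' it <- item_bank(2, list(c(-1, 1)))$items[[1]]
#' boundary_probabilities(it, 0) # plogis(2), plogis(-2)
#' @export
boundary_probabilities <- function(item, theta) {
  b <- item$thresholds
  p <- stats::plogis(item$discrimination * outer(theta, b, `-`))
  dimnames(p) <- list(NULL, paste0("P(X>=", seq_along(b) + 1L, ")"))
  p
}

#' GRM category probabilities
#'
#' Response-category probabilities `P(X = k | theta)`, `k = 1..K`, obtained
#' as adjacent differences of boundary probabilities (with the conventions
#' `P(X >= 1) = 1` and `P(X >= K+1) = 0`).
#'
#' @inheritParams boundary_probabilities
#' @return A `length(theta) x K` matrix; rows are nonnegative and sum to 1.
#' @examples
#' it <- item_bank(2, list(c(-1, 1)))$items[[1]]
#' category_probabilities(it, c(-2, 0, 2))
#' @export
category_probabilities <- function(item, theta) {
  K <- item$n_categories
  B <- cbind(1, boundary_probabilities(item, theta), 0)
  p <- B[, seq_len(K), drop = FALSE] - B[, seq_len(K) + 1L, drop = FALSE]
  dimnames(p) <- list(NULL, paste0("P", seq_len(K)))
  p
}

#' Item and test Fisher information
#'
#' Expected (Fisher) information contributed by an item at latent trait
#' `theta`: `I(theta) = sum_k (dP_k/dtheta)^2 / P_k`. Test information is the
#' sum of item informations over a set of items (local independence).
#'
#' @inheritParams boundary_probabilities
#' @return `item_information()`: a numeric vector the length of `theta`.
#' @examples
#' it <- item_bank(2, list(0))$items[[1]]
#' item_information(it, 0) # dichotomous closed form a^2 P (1 - P) = 1
#' @export
item_information <- function(item, theta) {
  a <- item$discrimination
  K <- item$n_categories
  B <- cbind(1, boundary_probabilities(item, theta), 0)
  P <- B[, seq_len(K), drop = FALSE] - B[, seq_len(K) + 1L, drop = FALSE]
  dB <- a * B * (1 - B)
  dP <- dB[, seq_len(K), drop = FALSE] - dB[, seq_len(K) + 1L, drop = FALSE]
  rowSums(dP^2 / pmax(P, 1e-12))
}

#' @rdname item_information
#' @param bank an [item_bank()].
#' @param items character vector of item ids to include (default: all).
#' @return `test_information()`: a numeric vector the length of `theta`.
#' @export
test_information <- function(bank, theta, items = names(bank$items)) {
  if (length(items) == 0L) stop("test information requires at least one item")
  info <- numeric(length(theta))
  for (id in items) info <- info + item_information(bank_item(bank, id), theta)
  info
}

# probabilities are clipped before logs so extreme theta cannot produce -Inf
.prob_floor <- 1e-12

#' Log-likelihood of a response vector
#'
#' Sum of log category probabilities over the answered items, at a vector of
#' latent-trait values. Responses are a named integer vector mapping item ids
#' to 1-based category indices; it may be partial (a CAT in progress) or
#' complete.
#'
#' @param responses named integer vector (`item_id -> category`).
#' @param bank an [item_bank()].
#' @param theta numeric vector of latent-trait values.
#' @return Numeric vector the length of `theta`; an empty response vector
#'   gives 0.
#' @export
response_loglik <- function(responses, bank, theta) {
  validate_responses(responses, bank)
  ll <- numeric(length(theta))
  for (id in names(responses)) {
    p <- category_probabilities(bank_item(bank, id), theta)[, responses[[id]]]
    ll <- ll + log(pmin(pmax(as.vector(p), .prob_floor), 1 - .prob_floor))
  }
  ll
}

validate_responses <- function(responses, bank) {
  if (length(responses) == 0L) return(invisible(responses))
  ids <- names(responses)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("responses must be a named vector (names are item ids)")
  if (anyDuplicated(ids)) stop("duplicate item ids in responses")
  for (id in ids) {
    item <- bank$items[[id]]
    if (is.null(item))
      stop(sprintf("response to unknown item '%s'", id))
    x <- responses[[id]]
    if (is.na(x) || x != as.integer(x) || x < 1L || x > item$n_categories)
      stop(sprintf("item '%s': category %s outside 1..%d", id,
                   format(x), item$n_categories))
  }
  invisible(responses)
}

#' @export
plot.item_bank <- function(x, theta = seq(-4, 4, length.out = 201),
                           type = c("information", "category"), item = NULL, ...) {
  type <- match.arg(type)
  if (type == "information") {
    info <- vapply(x$items, item_information, numeric(length(theta)), theta = theta)
    graphics::matplot(theta, info, type = "l", lty = 1,
                      xlab = expression(theta), ylab = "Fisher information",
                      main = "Item information curves", ...)
    graphics::legend("topright", legend = names(x$items), lty = 1,
                     col = seq_along(x$items), cex = 0.7, bty = "n")
  } else {
    if (is.null(item)) item <- names(x$items)[1L]
    p <- category_probabilities(bank_item(x, item), theta)
    graphics::matplot(theta, p, type = "l", lty = 1, ylim = c(0, 1),
                      xlab = expression(theta), ylab = "P(X = k)",
                      main = sprintf("Category response curves: %s", item), ...)
  }
  invisible(x)
}
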