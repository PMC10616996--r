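#' Fit a graded response model by marginal maximum likelihood
#'
#' Calibrates item discriminations and category thresholds from a person by
#' item matrix of ordinal responses using the Bock--Aitkin EM algorithm:
#' the latent trait is integrated out over a fixed standard-normal
#' population density on a Gauss--Legendre grid (the identification
#' constraint), expected category counts per quadrature node form the
#' E-step, and each item's parameters are updated by quasi-Newton
#' maximization of its expected complete-data log-likelihood. The update is
#' performed on `(log a, b_1, log diff(b))` so positivity of the slope and
#' strict ordering of the thresholds hold by construction.
#'
#' Missing responses (`NA`) are ignored in the per-person likelihood
#' product (missing-at-random). Response categories never observed in the
#' data are collapsed into their nearest observed neighbour (with a warning
#' and a recorded category map) because their thresholds are inestimable.
#'
#' @param data matrix or data.frame, persons in rows and items in columns;
#'   entries are 1-based ordinal categories, `NA` for missing. Column names
#'   are the item ids.
#' @param n_categories optional integer vector declaring the number of
#'   response categories per item; defaults to the per-item observed
#'   maximum.
#' @param n_quadrature number of Gauss--Legendre nodes (default 61).
#' @param quad_range latent-trait interval covered by the quadrature.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the change in marginal
#'   log-likelihood between successive EM iterations.
#' @param transform the [scale_transform()] attached to the fitted bank.
#' @param labels optional item wordings for the fitted bank.
#'
#' @return An object of class `"grm"`: a list with components
#'   \describe{
#'     \item{bank}{the fitted [item_bank()];}
#'     \item{loglik}{final marginal log-likelihood;}
#'     \item{loglik_trace}{marginal log-likelihood after each EM iteration
#'       (non-decreasing);}
#'     \item{n_iter, converged}{EM bookkeeping;}
#'     \item{category_maps}{per-item map from declared to fitted (possibly
#'       collapsed) categories;}
#'     \item{data}{the recoded response matrix used for fitting.}
#'   }
#'   Supported methods: `print`, `summary`, `coef`, `logLik`, `residuals`
#'   (observed vs model-expected category counts), `predict` (EAP scores
#'   for new response sets) and `simulate`.
#' @examples
#' bank <- make_fixture_bank(n_items = 4, n_categories = 3, seed = 1)
#' theta <- rnorm(300)
#' resp <- simulate_responses(bank, theta)
#' fit <- grm(resp, max_iter = 50)
#' coef(fit)
#' @export
grm <- function(data, n_categories = NULL, n_quadrature = 61,
                quad_range = c(-6, 6), max_iter = 500, tol = 1e-5,
                transform = scale_transform(), labels = NULL) {
  cl <- match.call()
  x <- as.matrix(data)
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) colnames(x) <- paste0("Q", seq_len(ncol(x)))
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("calibration requires at least 2 persons and 2 items")
  if (any(x < 1L, na.rm = TRUE))
    stop("response categories must be 1-based positive integers")
  if (n_quadrature < 11) stop("`n_quadrature` must be at least 11")

  rec <- recode_categories(x, n_categories)
  x <- rec$data
  K <- rec$K
  n_par <- sum(K)  # one slope + (K-1) thresholds per item
  if (nrow(x) < n_par)
    stop(sprintf("under-identified: %d persons cannot identify %d parameters",
                 nrow(x), n_par))

  gq <- pracma::gaussLegendre(n_quadrature, quad_range[1], quad_range[2])
  nodes <- gq$x
  wq <- gq$w * stats::dnorm(nodes)

  pars <- start_values(x, K)
  trace <- numeric(0)
  converged <- FALSE
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    e <- grm_estep(x, K, pars, nodes, wq)
    trace <- c(trace, e$loglik)
    for (i in seq_len(ncol(x)))
      pars[[i]] <- mstep_item(pars[[i]], e$r[[i]], nodes)
    if (is.finite(ll_old) && abs(e$loglik - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- e$loglik
  }
  if (!converged) {
    last_change <- if (length(trace) > 1) abs(diff(utils::tail(trace, 2))) else NA
    warning(sprintf("EM did not converge in %d iterations (last change %.2e)",
                    max_iter, last_change))
  }

  bank <- item_bank(
    discrimination = vapply(pars, function(p) exp(p[1]), numeric(1)),
    thresholds = lapply(pars, par_to_thresholds),
    ids = colnames(x),
    labels = labels,
    transform = transform,
    metadata = list(source = "grm() MML-EM calibration"))
  final <- grm_estep(x, K, pars, nodes, wq)
  structure(list(bank = bank, loglik = final$loglik, loglik_trace = trace,
                 n_iter = length(trace), converged = converged,
                 category_maps = rec$maps, data = x, n_persons = nrow(x),
                 quadrature = list(nodes = nodes, weights = wq),
                 call = cl),
            class = "grm")
}

# collapse never-observed categories into their nearest observed neighbour;
# returns recoded data, per-item category counts and the category maps
recode_categories <- function(x, n_categories) {
  n_items <- ncol(x)
  K <- integer(n_items)
  maps <- vector("list", n_items)
  names(maps) <- colnames(x)
  for (i in seq_len(n_items)) {
    v <- x[, i]
    obs <- sort(unique(v[!is.na(v)]))
    if (length(obs) < 2L)
      stop(sprintf("item '%s' has fewer than 2 observed categories", colnames(x)[i]))
    declared <- if (is.null(n_categories)) max(obs) else n_categories[i]
    map <- vapply(seq_len(declared), function(k)
      match(obs[which.min(abs(obs - k))], obs), integer(1))
    if (length(obs) < declared) {
      warning(sprintf(
        "item '%s': %d of %d categories never observed; collapsed into nearest neighbours",
        colnames(x)[i], declared - length(obs), declared))
    }
    x[, i] <- map[v]
    K[i] <- length(obs)
    maps[[i]] <- map
  }
  list(data = x, K = K, maps = maps)
}

# classic starting values: unit slope, thresholds at normal quantiles of the
# observed cumulative category proportions
start_values <- function(x, K) {
  lapply(seq_len(ncol(x)), function(i) {
    v <- x[!is.na(x[, i]), i]
    cum <- cumsum(tabulate(v, K[i]))[seq_len(K[i] - 1L)] / length(v)
    b <- stats::qnorm(pmin(pmax(cum, 0.02), 0.98))
    b <- cummax(b + seq_along(b) * 1e-3)  # enforce strict increase
    thresholds_to_par(1, b)
  })
}

thresholds_to_par <- function(a, b) {
  c(log(a), b[1], if (length(b) > 1) log(diff(b)))
}

par_to_thresholds <- function(par) {
  if (length(par) == 2L) par[2] else cumsum(c(par[2], exp(par[-(1:2)])))
}

par_category_probs <- function(par, nodes) {
  a <- exp(par[1])
  b <- par_to_thresholds(par)
  B <- cbind(1, stats::plogis(a * outer(nodes, b, `-`)), 0)
  Kk <- length(b) + 1L
  B[, seq_len(Kk), drop = FALSE] - B[, seq_len(Kk) + 1L, drop = FALSE]
}

# E-step: posterior node weights per person and expected category counts
# r[[i]] is a K_i x Q matrix of expected counts
grm_estep <- function(x, K, pars, nodes, wq) {
  n <- nrow(x)
  Q <- length(nodes)
  P <- lapply(seq_along(pars), function(i) par_category_probs(pars[[i]], nodes))
  L <- matrix(1, n, Q)
  for (i in seq_len(ncol(x))) {
    idx <- which(!is.na(x[, i]))
    # P[[i]] is Q x K; pick each person's category column, persons in rows
    if (length(idx)) L[idx, ] <- L[idx, ] * t(P[[i]][, x[idx, i], drop = FALSE])
  }
  num <- sweep(L, 2, wq, `*`)
  denom <- rowSums(num)
  W <- num / denom
  r <- vector("list", ncol(x))
  for (i in seq_len(ncol(x))) {
    idx <- which(!is.na(x[, i]))
    # one row per category (all of 1..K_i occur after recoding) -> K_i x Q
    r[[i]] <- rowsum(W[idx, , drop = FALSE], group = x[idx, i], reorder = TRUE)
  }
  list(loglik = sum(log(denom)), W = W, r = r)
}

# M-step for one item: quasi-Newton on the expected complete-data
# log-likelihood; a capped inner iteration count gives a generalized EM step
# that still never decreases the objective (started from current parameters)
mstep_item <- function(par, r, nodes) {
  obj <- function(p) {
    P <- pmax(par_category_probs(p, nodes), .prob_floor)
    -sum(t(r) * log(P))
  }
  fit <- stats::optim(par, obj, method = "BFGS",
                      control = list(maxit = 25, reltol = 1e-10))
  if (fit$value <= obj(par)) fit$par else par
}

#' Marginal log-likelihood of an item bank for observed data
#'
#' The MML objective: for each person, the log of the integral over the
#' latent trait of the response-pattern likelihood weighted by the
#' standard-normal population density, evaluated by Gauss--Legendre
#' quadrature. Persons with all responses missing contribute 0.
#'
#' @inheritParams grm
#' @param bank an [item_bank()] whose item ids match `colnames(data)`.
#' @export
marginal_loglik <- function(data, bank, n_quadrature = 61,
                            quad_range = c(-6, 6)) {
  x <- as.matrix(data)
  storage.mode(x) <- "integer"
  ids <- colnames(x)
  if (is.null(ids) || !all(ids %in% names(bank$items)))
    stop("column names of `data` must all be item ids of `bank`")
  gq <- pracma::gaussLegendre(n_quadrature, quad_range[1], quad_range[2])
  wq <- gq$w * stats::dnorm(gq$x)
  L <- matrix(1, nrow(x), length(gq$x))
  for (i in seq_along(ids)) {
    P <- category_probabilities(bank_item(bank, ids[i]), gq$x)  # Q x K
    idx <- which(!is.na(x[, i]))
    if (length(idx)) L[idx, ] <- L[idx, ] * t(P[, x[idx, i], drop = FALSE])
  }
  sum(log(rowSums(sweep(L, 2, wq, `*`))))
}

#' @export
print.grm <- function(x, ...) {
  cat("Graded response model fit (MML-EM)\n")
  cat(sprintf("  %d persons, %d items; logLik %.2f; %d EM iterations (%s)\n",
              x$n_persons, length(x$bank$items), x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  print(coef(x), digits = 3)
  invisible(x)
}

#' @export
coef.grm <- function(object, ...) coef(object$bank)

#' @export
logLik.grm <- function(object, ...) {
  structure(object$loglik,
            df = sum(vapply(object$bank$items, `[[`, 1L, "n_categories")),
            nobs = object$n_persons, class = "logLik")
}

#' Observed vs model-expected category counts
#'
#' For each item and category, the observed response count and the count
#' expected under the fitted model (the model probability integrated over
#' each person's posterior latent-trait distribution), with Pearson
#' residuals `(O - E) / sqrt(E)`. Expected counts per item sum to the
#' item's number of non-missing responses.
#'
#' @param object a fitted `"grm"`.
#' @param ... unused.
#' @return A data.frame with columns `item_id`, `category`, `observed`,
#'   `expected`, `residual`.
#' @export
residuals.grm <- function(object, ...) {
  x <- object$data
  nodes <- object$quadrature$nodes
  wq <- object$quadrature$weights
  pars <- lapply(object$bank$items, function(it)
    thresholds_to_par(it$discrimination, it$thresholds))
  e <- grm_estep(x, vapply(object$bank$items, `[[`, 1L, "n_categories"),
                 pars, nodes, wq)
  out <- NULL
  for (i in seq_len(ncol(x))) {
    item <- object$bank$items[[i]]
    idx <- which(!is.na(x[, i]))
    P <- par_category_probs(pars[[i]], nodes)           # Q x K
    mass <- colSums(e$W[idx, , drop = FALSE])           # posterior mass per node
    expected <- as.numeric(mass %*% P)
    observed <- tabulate(x[idx, i], item$n_categories)
    out <- rbind(out, data.frame(
      item_id = item$id, category = seq_len(item$n_categories),
      observed = observed, expected = expected,
      residual = (observed - expected) / sqrt(pmax(expected, .prob_floor)),
      stringsAsFactors = FALSE))
  }
  out
}

#' @export
summary.grm <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object, residuals = res,
                 max_abs_residual = max(abs(res$residual))),
            class = "summary.grm")
}

#' @export
print.summary.grm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Observed vs expected category counts: max |Pearson residual| %.2f\n",
              x$max_abs_residual))
  invisible(x)
}

#' EAP scores for new response sets
#'
#' @param object a fitted `"grm"`.
#' @param newdata matrix/data.frame of ordinal responses with item-id
#'   columns (defaults to the calibration data). Categories are passed
#'   through the calibration category maps, so data coded on the declared
#'   scale score correctly even when categories were collapsed during
#'   fitting.
#' @param grid quadrature from [eap_grid()].
#' @param ... unused.
#' @return data.frame with one row per person: `theta`, `se`, `score`,
#'   `score_se`, `n_items`.
#' @export
predict.grm <- function(object, newdata = NULL, grid = eap_grid(), ...) {
  x <- if (is.null(newdata)) object$data else as.matrix(newdata)
  storage.mode(x) <- "integer"
  ids <- colnames(x)
  if (!all(ids %in% names(object$bank$items)))
    stop("`newdata` has columns that are not items of the fitted bank")
  if (!is.null(newdata)) {
    for (i in seq_along(ids)) {
      map <- object$category_maps[[ids[i]]]
      v <- x[, i]
      bad <- which(!is.na(v) & (v < 1L | v > length(map)))
      if (length(bad))
        stop(sprintf("item '%s': category %d outside 1..%d (person %d)",
                     ids[i], v[bad[1]], length(map), bad[1]))
      x[, i] <- map[v]
    }
  }
  out <- t(apply(x, 1L, function(row) {
    resp <- structure(as.integer(row[!is.na(row)]),
                      names = ids[!is.na(row)])
    est <- eap_estimate(resp, object$bank, grid)
    c(theta = est$theta, se = est$se, score = est$score,
      score_se = est$score_se, n_items = est$n_items)
  }))
  as.data.frame(out)
}

#' @export
simulate.grm <- function(object, nsim = 1, seed = NULL,
                         theta = stats::rnorm(object$n_persons), ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, simulate_responses(object$bank, theta),
                   simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.grm <- function(x, ...) plot(x$bank, ...)
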