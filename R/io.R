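#' Read and write item banks as JSON
#'
#' The interchange format for calibrated parameters is a JSON document:
#' ```
#' {
#'   "metadata": {"instrument": "...", "version": "...",
#'                "transform": {"slope": 12.5, "offset": 50}},
#'   "items": [{"id": "Q1", "label": "...", "n_categories": 7,
#'              "discrimination": 2.3,
#'              "thresholds": [-3.0, -1.9, ...]}, ...]
#' }
#' ```
#' Parameters are written with full precision, so `read_item_bank()`
#' round-trips a written bank losslessly. Files may also carry parameters
#' in the slope--intercept dialect (`"intercepts"` `d_k` with
#' `P(X >= k+1) = plogis(a * theta + d_k)` instead of `"thresholds"`); with
#' `parameterization = "intercept"` these are converted on load via
#' `b_k = -d_k / a`.
#'
#' @param path file path.
#' @param parameterization `"threshold"` (default) or `"intercept"`.
#' @return `read_item_bank()`: an [item_bank()].
#' @export
read_item_bank <- function(path, parameterization = c("threshold", "intercept")) {
  parameterization <- match.arg(parameterization)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$items) || length(doc$items) == 0L)
    stop(sprintf("'%s': no items in bank file", path))
  meta <- doc$metadata
  tr <- if (!is.null(meta$transform)) {
    scale_transform(meta$transform$slope, meta$transform$offset)
  } else {
    scale_transform()
  }
  meta$transform <- NULL
  items <- lapply(doc$items, function(it) {
    id <- it$id %||% stop("bank file item without an 'id'")
    a <- as.numeric(it$discrimination)
    b <- if (parameterization == "intercept") {
      d <- as.numeric(unlist(it$intercepts %||% it$thresholds))
      -d / a
    } else {
      as.numeric(unlist(it$thresholds))
    }
    declared <- it$n_categories %||% (length(b) + 1L)
    if (declared != length(b) + 1L)
      stop(sprintf("item '%s': n_categories %d inconsistent with %d thresholds",
                   id, declared, length(b)))
    tryCatch(new_item(id, it$label %||% id, a, b),
             error = function(e) stop(sprintf("bank file '%s': %s",
                                              path, conditionMessage(e)),
                                      call. = FALSE))
  })
  ids <- vapply(items, `[[`, "", "id")
  if (anyDuplicated(ids)) stop(sprintf("'%s': duplicate item ids", path))
  names(items) <- ids
  structure(list(items = items, transform = tr,
                 metadata = if (is.null(meta)) list() else meta),
            class = "item_bank")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_item_bank
#' @param bank an [item_bank()] to serialize.
#' @export
write_item_bank <- function(bank, path) {
  doc <- list(
    metadata = c(bank$metadata,
                 list(transform = list(slope = bank$transform$slope,
                                       offset = bank$transform$offset))),
    items = lapply(unname(bank$items), function(it)
      list(id = it$id, label = it$label, n_categories = it$n_categories,
           discrimination = it$discrimination, thresholds = it$thresholds)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write ordinal response matrices as CSV
#'
#' Responses travel as a wide CSV: a `person_id` column plus one column per
#' item id; cells are 1-based categories and empty cells are missing. When
#' a bank is supplied the header is checked against it and every category
#' is range-checked, with errors addressed by row and column.
#'
#' @param path file path.
#' @param bank optional [item_bank()] to validate against.
#' @param complete_cases if `TRUE`, drop persons with any missing response
#'   (calibration on complete response sets).
#' @return `read_responses()`: an integer matrix, persons in rows (named by
#'   `person_id`), items in columns.
#' @export
read_responses <- function(path, bank = NULL, complete_cases = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"person_id" %in% names(df))
    stop(sprintf("'%s': missing 'person_id' column", path))
  ids <- setdiff(names(df), "person_id")
  if (!is.null(bank)) {
    unknown <- setdiff(ids, names(bank$items))
    if (length(unknown))
      stop(sprintf("'%s': columns not in bank: %s", path,
                   paste(unknown, collapse = ", ")))
  }
  m <- as.matrix(df[ids])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$person_id)
  if (!is.null(bank)) {
    for (j in seq_along(ids)) {
      K <- bank$items[[ids[j]]]$n_categories
      v <- m[, j]
      bad <- which(!is.na(v) & (v < 1L | v > K))
      if (length(bad))
        stop(sprintf("'%s': row %d, item '%s': category %d outside 1..%d",
                     path, bad[1], ids[j], v[bad[1]], K))
    }
  }
  if (complete_cases) m <- m[stats::complete.cases(m), , drop = FALSE]
  m
}

#' @rdname read_responses
#' @param responses integer matrix with item-id columns and person ids as
#'   rownames.
#' @export
write_responses <- function(responses, path) {
  df <- data.frame(person_id = rownames(responses) %||%
                     paste0("P", seq_len(nrow(responses))),
                   responses, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write simulation records as CSV
#'
#' One row per simulated respondent: true trait, full-length and CAT
#' estimates on both scales, item count, stop reason, and the ordered list
#' of administered items (semicolon-separated). `read_sim_results()`
#' reloads the table with the records and item lists reconstructed, so an
#' [agreement_report()] can be computed from a stored run.
#'
#' @param sim a `"cat_sim"`.
#' @param path file path.
#' @export
write_sim_results <- function(sim, path) {
  df <- sim$records
  df$items_administered <- vapply(sim$items_administered,
                                  paste, "", collapse = ";")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sim_results
#' @export
read_sim_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  items <- strsplit(df$items_administered, ";", fixed = TRUE)
  df$items_administered <- NULL
  structure(list(records = df, items_administered = items,
                 bank = NULL, control = NULL, dist = NULL, seed = NULL),
            class = "cat_sim")
}

#' Write an agreement report as JSON
#'
#' @param report an [agreement_report()].
#' @param path file path.
#' @export
write_agreement_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
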