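#' Define a psychometric scale
#'
#' A scale definition bundles everything the scoring rules need: how many
#' items there are, the ordinal response range, how many valid (non-missing)
#' items are required before a mean score may be computed, and — for screening
#' instruments — the clinical cut-off applied to the mean score.
#'
#' @param name Label used for the outcome in all result tables.
#' @param item_prefix Prefix of the item columns in delimited tables; item
#'   `k` lives in column `<item_prefix>_<k>` (1-based).
#' @param n_items Number of items.
#' @param response_min,response_max Integer bounds of the ordinal response
#'   range (inclusive).
#' @param min_valid_items Minimum number of non-missing items required to
#'   score a participant; below this the score is `NA`.
#' @param caseness_cutoff Optional cut-off on the mean score; scores at or
#'   above the cut-off (inclusive) are flagged as cases. `NULL` for scales
#'   without an agreed cut-off.
#'
#' @return An object of class `scale_definition`.
#' @seealso [hscl10()], [css4()] for the two built-in instruments.
#' @export
scale_definition <- function(name, item_prefix, n_items,
                             response_min, response_max,
                             min_valid_items, caseness_cutoff = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(item_prefix), length(item_prefix) == 1L)
  n_items <- as.integer(n_items)
  response_min <- as.integer(response_min)
  response_max <- as.integer(response_max)
  min_valid_items <- as.integer(min_valid_items)
  if (response_min >= response_max) {
    stop("`response_min` must be strictly below `response_max`", call. = FALSE)
  }
  if (min_valid_items < 1L || min_valid_items > n_items) {
    stop("`min_valid_items` must lie in 1..n_items", call. = FALSE)
  }
  if (!is.null(caseness_cutoff)) {
    stopifnot(is.numeric(caseness_cutoff), length(caseness_cutoff) == 1L)
  }
  structure(
    list(name = name, item_prefix = item_prefix, n_items = n_items,
         response_min = response_min, response_max = response_max,
         min_valid_items = min_valid_items, caseness_cutoff = caseness_cutoff),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items, responses %d-%d, >=%d valid to score",
              x$name, x$n_items, x$response_min, x$response_max,
              x$min_valid_items))
  if (!is.null(x$caseness_cutoff)) {
    cat(sprintf(", caseness at mean >= %.2f", x$caseness_cutoff))
  }
  cat("\n")
  invisible(x)
}

#' The 10-item Hopkins Symptom Checklist (anxiety/depression)
#'
#' Ten symptom items rated 1 (not bothered) to 4 (bothered a great deal).
#' The score is the mean of valid items; one missing item is tolerated
#' (at least 9 of 10 required). A mean score of 1.85 or above (inclusive)
#' indicates a clinically significant symptom level.
#'
#' @return A [scale_definition()].
#' @export
hscl10 <- function() {
  scale_definition("hscl10", "hscl", n_items = 10L,
                   response_min = 1L, response_max = 4L,
                   min_valid_items = 9L, caseness_cutoff = 1.85)
}

#' The 4-item Crisis Support Scale (perceived social support)
#'
#' Four support items rated 1 (never) to 5 (very often/always). The score is
#' the mean of valid items; one missing item is tolerated (at least 3 of 4
#' required). No caseness cut-off is defined for this instrument.
#'
#' @return A [scale_definition()].
#' @export
css4 <- function() {
  scale_definition("css4", "css", n_items = 4L,
                   response_min = 1L, response_max = 5L,
                   min_valid_items = 3L, caseness_cutoff = NULL)
}

#' Names of the item columns for a scale
#'
#' @param definition A [scale_definition()].
#' @return Character vector `<item_prefix>_1` .. `<item_prefix>_<n_items>`.
#' @export
item_columns <- function(definition) {
  stopifnot(inherits(definition, "scale_definition"))
  paste0(definition$item_prefix, "_", seq_len(definition$n_items))
}

.check_responses <- function(x, definition, what = "response") {
  bad <- which(!is.na(x) &
                 (x < definition$response_min | x > definition$response_max |
                    x != round(x)))
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s for scale '%s' at item index %d (value %s): must be an integer in %d..%d",
                 what, definition$name, bad[1L], format(x[bad[1L]]),
                 definition$response_min, definition$response_max),
         call. = FALSE)
  }
  invisible(x)
}

#' Score one participant's responses on a scale
#'
#' The score is the arithmetic mean of the non-missing responses, provided at
#' least `min_valid_items` of them are present; otherwise the score is `NA`.
#' For scales with a caseness cut-off, `case` is `TRUE` when the score is at
#' or above the cut-off (the comparison is inclusive: a score exactly at the
#' cut-off is a case).
#'
#' @param items Numeric vector of length `n_items`, in item order, with `NA`
#'   for missing responses. Present responses must be integers within the
#'   scale's response range.
#' @param definition A [scale_definition()].
#'
#' @return A list with `value` (mean score or `NA`), `n_valid` (number of
#'   non-missing items) and `case` (`TRUE`/`FALSE`, or `NA` when the scale
#'   has no cut-off or the score is absent).
#' @examples
#' score_scale(c(2, 2, 2, 2, 2, 1, 1, 1, 2, 2), hscl10())
#' @export
score_scale <- function(items, definition) {
  stopifnot(inherits(definition, "scale_definition"))
  if (length(items) != definition$n_items) {
    stop(sprintf("scale '%s' expects %d items, got %d",
                 definition$name, definition$n_items, length(items)),
         call. = FALSE)
  }
  .check_responses(items, definition)
  n_valid <- sum(!is.na(items))
  value <- if (n_valid >= definition$min_valid_items) {
    mean(items, na.rm = TRUE)
  } else {
    NA_real_
  }
  case <- if (is.null(definition$caseness_cutoff) || is.na(value)) {
    NA
  } else {
    value >= definition$caseness_cutoff
  }
  list(value = value, n_valid = n_valid, case = case)
}

#' Score a table of participants on one scale
#'
#' Applies the scale's scoring rules row-wise to the item columns
#' `<item_prefix>_1` .. `<item_prefix>_<n_items>` and appends the columns
#' `<name>_score`, `<name>_n_valid` and (for scales with a cut-off)
#' `<name>_case`.
#'
#' @param data A data frame holding the scale's item columns.
#' @param definition A [scale_definition()].
#' @return `data` with the score columns appended.
#' @export
score_responses <- function(data, definition) {
  stopifnot(is.data.frame(data), inherits(definition, "scale_definition"))
  cols <- item_columns(definition)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop(sprintf("item column '%s' for scale '%s' is absent from the data",
                 missing_cols[1L], definition$name), call. = FALSE)
  }
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  for (j in seq_len(ncol(m))) .check_responses(m[, j], definition)
  n_valid <- rowSums(!is.na(m))
  value <- rowMeans(m, na.rm = TRUE)
  value[n_valid < definition$min_valid_items] <- NA_real_
  value[n_valid == 0L] <- NA_real_
  data[[paste0(definition$name, "_score")]] <- value
  data[[paste0(definition$name, "_n_valid")]] <- as.integer(n_valid)
  if (!is.null(definition$caseness_cutoff)) {
    data[[paste0(definition$name, "_case")]] <- value >= definition$caseness_cutoff
  }
  tibble::as_tibble(data)
}

#' Cronbach's alpha (coefficient alpha)
#'
#' Internal consistency of a persons-by-items matrix, computed on listwise
#' complete rows with the standard formula
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right)}
#' where \eqn{s_j^2} are the unbiased (n-1 denominator) item variances and
#' \eqn{s_T^2} is the unbiased variance of the row totals.
#'
#' @param item_matrix Numeric matrix or data frame, one row per person, one
#'   column per item. Rows with any missing value are dropped.
#' @return A single number, at most 1.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("Cronbach's alpha needs at least 2 items", call. = FALSE)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) {
    stop("Cronbach's alpha needs at least 3 complete cases", call. = FALSE)
  }
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) {
    stop("Cronbach's alpha is undefined: total-score variance is zero",
         call. = FALSE)
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
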