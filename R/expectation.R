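#' Restrict the cohort to participants comparable with the reference sample
#'
#' Retains cohort rows whose age is known and lies inside the reference
#' sample's age range; everyone else is excluded with a logged reason
#' (`missing_age`, `under_age` or `over_age`). Ages are completed years and
#' the range is closed on both ends.
#'
#' @param cohort Data frame with at least `id` and `age` columns; `age` may
#'   be `NA`.
#' @param reference_age_range Inclusive integer interval `c(lo, hi)`.
#' @return A list with `eligible` (the retained rows) and `exclusions`
#'   (tibble of `id`, `age`, `reason`; zero rows when nothing was excluded).
#'   An empty eligible table is legal and is flagged with a warning.
#' @export
filter_eligible <- function(cohort, reference_age_range = c(18L, 74L)) {
  stopifnot(is.data.frame(cohort), "age" %in% names(cohort))
  lo <- reference_age_range[1L]
  hi <- reference_age_range[2L]
  age <- cohort$age
  reason <- rep(NA_character_, nrow(cohort))
  reason[is.na(age)] <- "missing_age"
  reason[!is.na(age) & age < lo] <- "under_age"
  reason[!is.na(age) & age > hi] <- "over_age"
  keep <- is.na(reason)
  exclusions <- tibble::tibble(
    id = if ("id" %in% names(cohort)) cohort$id[!keep] else which(!keep),
    age = age[!keep],
    reason = reason[!keep]
  )
  eligible <- tibble::as_tibble(cohort[keep, , drop = FALSE])
  if (nrow(eligible) == 0L) {
    warning("no cohort participants are eligible for comparison", call. = FALSE)
  }
  list(eligible = eligible, exclusions = exclusions)
}

#' Build the age-by-gender expectation table from a scored reference sample
#'
#' For every (gender, age) combination present in the reference sample and
#' every outcome, computes the number of scored persons, their mean score
#' and — for outcomes with a caseness cut-off — the proportion of cases.
#' Rows whose score is absent for an outcome are dropped for that outcome
#' only; a person can contribute to one outcome's cell but not another's.
#'
#' @param reference Reference table already scored with [score_responses()]
#'   (columns `<name>_score` and, where applicable, `<name>_case`).
#' @param outcomes List of [scale_definition()]s.
#' @return A tibble with columns `outcome`, `gender`, `age`, `n`,
#'   `mean_score`, `prop_case` (`NA` for outcomes without a cut-off), sorted
#'   by outcome, gender, age.
#' @export
build_stratum_table <- function(reference, outcomes = list(hscl10(), css4())) {
  stopifnot(is.data.frame(reference))
  if (nrow(reference) == 0L) stop("reference sample is empty", call. = FALSE)
  for (col in c("gender", "age")) {
    if (!col %in% names(reference)) {
      stop(sprintf("reference table lacks required column '%s'", col), call. = FALSE)
    }
  }
  pieces <- lapply(outcomes, function(def) {
    score_col <- paste0(def$name, "_score")
    if (!score_col %in% names(reference)) {
      stop(sprintf("outcome column '%s' is absent; score the reference first",
                   score_col), call. = FALSE)
    }
    has_cut <- !is.null(def$caseness_cutoff)
    df <- tibble::tibble(
      gender = reference$gender,
      age = as.integer(reference$age),
      score = reference[[score_col]],
      case = if (has_cut) reference[[paste0(def$name, "_case")]] else NA
    )
    df <- df[!is.na(df$score), , drop = FALSE]
    out <- df |>
      dplyr::group_by(.data$gender, .data$age) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_score = mean(.data$score),
        prop_case = if (has_cut) mean(.data$case) else NA_real_,
        .groups = "drop"
      )
    out$outcome <- def$name
    out
  })
  dplyr::bind_rows(pieces) |>
    dplyr::select("outcome", "gender", "age", "n", "mean_score", "prop_case") |>
    dplyr::arrange(.data$outcome, .data$gender, .data$age)
}

#' Ascribe expected scores to cohort participants from the stratum table
#'
#' Each participant receives, per outcome, the mean score (and caseness
#' proportion, where defined) of the reference cell with the same gender and
#' exact age in completed years. When that cell is empty — which can happen
#' inside bootstrap resamples even if the full reference covers every age —
#' the neighbouring cells at age distance 1, 2, ... within the same gender
#' are searched; at the first distance with any reference persons, all
#' persons found there (both sides pooled, weighted by cell size) supply the
#' expectation, and the distance is recorded in `fallback_distance`. Beyond
#' `fallback_max_distance` years the participant cannot be matched and the
#' call fails, naming the orphan.
#'
#' @param cohort Eligible cohort rows with `id`, `gender`, `age`.
#' @param stratum_table A [build_stratum_table()] result.
#' @param fallback_max_distance Maximum age distance (years) searched when
#'   the exact cell is empty.
#' @return A tibble with one row per participant per outcome: `id`,
#'   `outcome`, `expected_score`, `expected_prop_case`, `matched_gender`,
#'   `matched_age`, `fallback_distance` (0 for an exact match).
#' @export
ascribe_expected <- function(cohort, stratum_table, fallback_max_distance = 5L) {
  stopifnot(is.data.frame(cohort), is.data.frame(stratum_table))
  if (nrow(stratum_table) == 0L) {
    stop("stratum table is empty; cannot ascribe expected values", call. = FALSE)
  }
  missing_gender <- setdiff(unique(cohort$gender), unique(stratum_table$gender))
  if (length(missing_gender) > 0L) {
    stop(sprintf("gender '%s' occurs in the cohort but not in the stratum table",
                 missing_gender[1L]), call. = FALSE)
  }
  outcomes <- unique(stratum_table$outcome)
  res <- lapply(outcomes, function(oc) {
    tab <- stratum_table[stratum_table$outcome == oc, , drop = FALSE]
    n_row <- nrow(cohort)
    exp_score <- numeric(n_row)
    exp_prop <- numeric(n_row)
    dist <- integer(n_row)
    for (i in seq_len(n_row)) {
      g <- cohort$gender[i]
      a <- as.integer(cohort$age[i])
      sub <- tab[tab$gender == g, , drop = FALSE]
      hit <- sub[sub$age == a, , drop = FALSE]
      d <- 0L
      while (nrow(hit) == 0L && d < fallback_max_distance) {
        d <- d + 1L
        hit <- sub[sub$age == a - d | sub$age == a + d, , drop = FALSE]
      }
      if (nrow(hit) == 0L) {
        stop(sprintf("participant '%s' (%s, age %d): no reference cell within %d years",
                     as.character(cohort$id[i]), g, a, fallback_max_distance),
             call. = FALSE)
      }
      exp_score[i] <- stats::weighted.mean(hit$mean_score, hit$n)
      exp_prop[i] <- if (all(is.na(hit$prop_case))) NA_real_ else
        stats::weighted.mean(hit$prop_case, hit$n)
      dist[i] <- d
    }
    tibble::tibble(
      id = cohort$id,
      outcome = oc,
      expected_score = exp_score,
      expected_prop_case = exp_prop,
      matched_gender = cohort$gender,
      matched_age = as.integer(cohort$age),
      fallback_distance = dist
    )
  })
  dplyr::bind_rows(res)
}
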