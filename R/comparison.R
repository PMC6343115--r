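#' Observed-versus-expected comparison estimates
#'
#' For every outcome and subgroup, summarizes the participants who carry both
#' an observed score and an expected value:
#' * `observed_mean`, `expected_mean` and their difference `mean_diff`;
#' * `mean_ratio`, the ratio of the two means (`observed_mean /
#'   expected_mean`) — the headline ratio — alongside
#'   `mean_ratio_participant`, the mean of the per-participant ratios, kept
#'   as an audited companion quantity;
#' * `effect_size`, the standardized mean difference `mean_diff /
#'   sd_observed`, where `sd_observed` is the sample standard deviation
#'   (n-1) of the observed scores in the subgroup being summarized;
#' * for outcomes with a caseness cut-off, the observed proportion of cases,
#'   the mean expected caseness probability and their difference
#'   (`prop_diff`, the excess caseness).
#'
#' Subgroups are `total`, each gender, and — when the cohort carries a
#' `group` column — each exposure group. Empty subgroups are dropped with a
#' warning.
#'
#' @param cohort Scored eligible cohort ([score_responses()] applied), with
#'   `id`, `gender` and optionally `group`.
#' @param expected An [ascribe_expected()] result aligned by `id`.
#' @param outcomes List of [scale_definition()]s.
#' @return A tibble with one row per outcome and subgroup.
#' @export
compare <- function(cohort, expected, outcomes = list(hscl10(), css4())) {
  stopifnot(is.data.frame(cohort), is.data.frame(expected))
  subgroups <- .subgroup_masks(cohort)
  rows <- list()
  for (def in outcomes) {
    score_col <- paste0(def$name, "_score")
    if (!score_col %in% names(cohort)) {
      stop(sprintf("cohort lacks score column '%s'", score_col), call. = FALSE)
    }
    exp_oc <- expected[expected$outcome == def$name, , drop = FALSE]
    e <- exp_oc[match(cohort$id, exp_oc$id), , drop = FALSE]
    obs <- cohort[[score_col]]
    has_cut <- !is.null(def$caseness_cutoff)
    case <- if (has_cut) cohort[[paste0(def$name, "_case")]] else NULL
    for (sg in names(subgroups)) {
      mask <- subgroups[[sg]]
      keep <- mask & !is.na(obs)
      if (!any(keep)) {
        warning(sprintf("subgroup '%s' has no scored participants for outcome '%s'; estimate omitted",
                        sg, def$name), call. = FALSE)
        next
      }
      if (anyNA(e$expected_score[keep])) {
        stop(sprintf("expected values missing for scored participants (outcome '%s', subgroup '%s')",
                     def$name, sg), call. = FALSE)
      }
      est <- .comparison_row(obs[keep], e$expected_score[keep],
                             if (has_cut) case[keep] else NULL,
                             if (has_cut) e$expected_prop_case[keep] else NULL)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        outcome = def$name, subgroup = sg, !!!est)
    }
  }
  dplyr::bind_rows(rows)
}

# Point estimates for one aligned observed/expected vector pair.
# Shared by compare() and the bootstrap replicate loop so that the
# point-estimate path and the resampling path cannot drift apart.
.comparison_row <- function(obs, exp_score, case = NULL, exp_prop = NULL) {
  n <- length(obs)
  om <- mean(obs)
  em <- mean(exp_score)
  if (any(exp_score == 0)) {
    stop("expected score of 0 encountered; per-participant ratio undefined",
         call. = FALSE)
  }
  sd_obs <- if (n >= 2L) stats::sd(obs) else NA_real_
  list(
    n = n,
    observed_mean = om,
    expected_mean = em,
    mean_diff = om - em,
    mean_ratio = om / em,
    mean_ratio_participant = mean(obs / exp_score),
    sd_observed = sd_obs,
    effect_size = if (isTRUE(sd_obs > 0)) (om - em) / sd_obs else NA_real_,
    observed_prop_case = if (is.null(case)) NA_real_ else mean(case),
    expected_prop_case = if (is.null(exp_prop)) NA_real_ else mean(exp_prop),
    prop_diff = if (is.null(case)) NA_real_ else mean(case) - mean(exp_prop)
  )
}

.subgroup_masks <- function(cohort) {
  masks <- list(total = rep(TRUE, nrow(cohort)))
  for (g in sort(unique(cohort$gender))) {
    masks[[g]] <- cohort$gender == g
  }
  if ("group" %in% names(cohort)) {
    for (g in sort(unique(cohort$group))) {
      masks[[g]] <- cohort$group == g
    }
  }
  masks
}

#' Per-participant observed/expected ratios
#'
#' One ratio per scored participant per outcome, carrying the gender and
#' group labels needed for the ratio dot-plots. A ratio of 1 means the
#' participant sits exactly at the expected level; above 1, higher than
#' expected.
#'
#' @inheritParams compare
#' @return A tibble with `id`, `outcome`, `gender`, `group` (if present),
#'   `observed`, `expected`, `ratio`.
#' @export
per_participant_ratios <- function(cohort, expected,
                                   outcomes = list(hscl10(), css4())) {
  rows <- lapply(outcomes, function(def) {
    score_col <- paste0(def$name, "_score")
    exp_oc <- expected[expected$outcome == def$name, , drop = FALSE]
    e <- exp_oc[match(cohort$id, exp_oc$id), , drop = FALSE]
    obs <- cohort[[score_col]]
    keep <- !is.na(obs)
    if (any(e$expected_score[keep] == 0)) {
      stop("expected score of 0 encountered; ratio undefined", call. = FALSE)
    }
    out <- tibble::tibble(
      id = cohort$id[keep],
      outcome = def$name,
      gender = cohort$gender[keep],
      observed = obs[keep],
      expected = e$expected_score[keep],
      ratio = obs[keep] / e$expected_score[keep]
    )
    if ("group" %in% names(cohort)) {
      out$group <- cohort$group[keep]
      out <- out[c("id", "outcome", "gender", "group", "observed", "expected", "ratio")]
    }
    out
  })
  dplyr::bind_rows(rows)
}
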