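#' Round the way the reporting layer prints
#'
#' Half-up decimal rounding (2.5 -> 3, -2.5 -> -3), used when result tables
#' are formatted for reporting. All internal computation stays at full
#' precision; only the reporting layer rounds.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
report_round <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage as printed in a report
#'
#' `100 * numerator / denominator`, rounded half-up to `digits` decimals.
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places (default 1).
#' @return A percentage on the 0-100 scale.
#' @export
report_percent <- function(numerator, denominator, digits = 1L) {
  report_round(100 * numerator / denominator, digits)
}

#' Configure an end-to-end pipeline run
#'
#' Exactly one of `cohort_path`/`reference_path` (delimited input tables) or
#' `synthetic` (a [synthetic_config()]) must be supplied.
#'
#' @param cohort_path,reference_path Paths to the cohort and reference CSV
#'   tables (missing items as empty fields), or `NULL`.
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param outcomes List of [scale_definition()]s.
#' @param bootstrap A [bootstrap_config()].
#' @param output_dir Directory the result bundle is written into.
#' @param make_plots Write the ratio dot-plots.
#' @param verbose Print progress to the console.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL, reference_path = NULL,
                            synthetic = NULL,
                            outcomes = list(hscl10(), css4()),
                            bootstrap = bootstrap_config(),
                            output_dir = "results",
                            make_plots = TRUE,
                            verbose = TRUE) {
  has_paths <- !is.null(cohort_path) || !is.null(reference_path)
  if (has_paths && (is.null(cohort_path) || is.null(reference_path))) {
    stop("supply both `cohort_path` and `reference_path`, or neither", call. = FALSE)
  }
  if (has_paths == !is.null(synthetic)) {
    stop("exactly one of {input paths, synthetic config} must be active", call. = FALSE)
  }
  structure(
    list(cohort_path = cohort_path, reference_path = reference_path,
         synthetic = synthetic, outcomes = outcomes, bootstrap = bootstrap,
         output_dir = output_dir, make_plots = make_plots, verbose = verbose),
    class = "pipeline_config"
  )
}

.validate_input_table <- function(data, outcomes, what, need_group) {
  required <- c("id", "age", "gender", if (need_group) "group",
                unlist(lapply(outcomes, item_columns)))
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s table lacks required column '%s'", what, missing_cols[1L]),
         call. = FALSE)
  }
  invisible(data)
}

#' Run the full observed-versus-expected pipeline
#'
#' Reads (or generates) the two tables, scores both scales, restricts the
#' cohort to the reference age range, builds the age-by-gender expectation
#' table, ascribes expected values, computes the comparison estimates,
#' attaches doubly-stratified bootstrap-percentile intervals, and writes
#' every intermediate and final table (plus the ratio plots and a run log)
#' into the output directory. With a fixed seed the result tables are
#' reproducible byte for byte; timestamps are confined to the log.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`cohort`,
#'   `reference`, `eligible`, `exclusions`, `stratum_table`, `expected`,
#'   `estimates`, `ci`, `ratios`, `alpha`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outcomes <- config$outcomes
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  log_lines <- c(sprintf("run started %s", format(Sys.time())))

  if (!is.null(config$synthetic)) {
    say("generating synthetic tables (seed %d)", config$synthetic$seed)
    reference <- generate_reference(config$synthetic, outcomes)
    cohort <- generate_cohort(config$synthetic, outcomes)
    ref_range <- config$synthetic$reference_age_range
    log_lines <- c(log_lines,
                   sprintf("synthetic data: n_reference=%d n_cohort=%d seed=%d",
                           config$synthetic$n_reference, config$synthetic$n_cohort,
                           config$synthetic$seed))
  } else {
    say("reading input tables")
    reference <- readr::read_csv(
      config$reference_path, na = "",
      col_types = readr::cols(id = "c", gender = "c", .default = "d"))
    cohort <- readr::read_csv(
      config$cohort_path, na = "",
      col_types = readr::cols(id = "c", gender = "c", group = "c",
                              .default = "d"))
    ref_range <- range(reference$age, na.rm = TRUE)
  }
  .validate_input_table(reference, outcomes, "reference", need_group = FALSE)
  .validate_input_table(cohort, outcomes, "cohort", need_group = TRUE)

  say("scoring %d reference and %d cohort rows", nrow(reference), nrow(cohort))
  for (def in outcomes) {
    reference <- score_responses(reference, def)
    cohort <- score_responses(cohort, def)
  }
  alpha <- lapply(outcomes, function(def) {
    tibble::tibble(
      outcome = def$name,
      alpha_reference = cronbach_alpha(reference[item_columns(def)]),
      alpha_cohort = cronbach_alpha(cohort[item_columns(def)])
    )
  }) |> dplyr::bind_rows()

  elig <- filter_eligible(cohort, ref_range)
  log_lines <- c(log_lines,
                 sprintf("eligibility: %d of %d cohort rows retained (%d excluded)",
                         nrow(elig$eligible), nrow(cohort), nrow(elig$exclusions)))

  say("building expectation table and estimates")
  stratum_table <- build_stratum_table(reference, outcomes)
  expected <- ascribe_expected(elig$eligible, stratum_table,
                               config$bootstrap$fallback_max_distance)
  n_fallback <- sum(expected$fallback_distance > 0)
  if (n_fallback > 0) {
    log_lines <- c(log_lines,
                   sprintf("WARNING: %d expected values used the age fallback", n_fallback))
  }
  estimates <- compare(elig$eligible, expected, outcomes)
  ratios <- per_participant_ratios(elig$eligible, expected, outcomes)

  say("bootstrap: %d resamples", config$bootstrap$n_resamples)
  ci <- run_bootstrap(elig$eligible, reference, outcomes, config$bootstrap)
  shortfall <- config$bootstrap$n_resamples - ci$n_effective_resamples
  if (any(shortfall > 0)) {
    log_lines <- c(log_lines,
                   sprintf("WARNING: up to %d resamples dropped per estimand", max(shortfall)))
  }

  out <- config$output_dir
  files <- c(
    scored_cohort = file.path(out, "scored_cohort.csv"),
    scored_reference = file.path(out, "scored_reference.csv"),
    exclusions = file.path(out, "exclusions.csv"),
    stratum_table = file.path(out, "stratum_table.csv"),
    expected = file.path(out, "expected_values.csv"),
    estimates = file.path(out, "comparison_estimates.csv"),
    ci = file.path(out, "bootstrap_ci.csv"),
    ratios = file.path(out, "ratios.csv"),
    alpha = file.path(out, "cronbach_alpha.csv")
  )
  readr::write_csv(cohort, files[["scored_cohort"]], na = "")
  readr::write_csv(reference, files[["scored_reference"]], na = "")
  readr::write_csv(elig$exclusions, files[["exclusions"]], na = "")
  readr::write_csv(stratum_table, files[["stratum_table"]], na = "")
  readr::write_csv(expected, files[["expected"]], na = "")
  readr::write_csv(estimates, files[["estimates"]], na = "")
  readr::write_csv(ci, files[["ci"]], na = "")
  readr::write_csv(ratios, files[["ratios"]], na = "")
  readr::write_csv(alpha, files[["alpha"]], na = "")

  if (config$make_plots) {
    for (def in outcomes) {
      for (panel in c("gender", if ("group" %in% names(ratios)) "group")) {
        p <- plot_ratios(ratios, def$name, panel_by = panel)
        stem <- file.path(out, sprintf("ratios_%s_by_%s", def$name, panel))
        ggplot2::ggsave(paste0(stem, ".pdf"), p, width = 7, height = 3.5)
        try(suppressMessages(
          ggplot2::ggsave(paste0(stem, ".png"), p, width = 7, height = 3.5, dpi = 150)),
          silent = TRUE)
        files[[paste0("plot_", def$name, "_", panel)]] <- paste0(stem, ".pdf")
      }
    }
  }

  log_lines <- c(log_lines,
                 sprintf("bootstrap: B=%d level=%.2f seed=%d",
                         config$bootstrap$n_resamples,
                         config$bootstrap$confidence_level,
                         config$bootstrap$seed),
                 sprintf("run finished %s", format(Sys.time())))
  writeLines(log_lines, file.path(out, "run_log.txt"))
  say("done; results in %s", out)

  invisible(list(cohort = cohort, reference = reference,
                 eligible = elig$eligible, exclusions = elig$exclusions,
                 stratum_table = stratum_table, expected = expected,
                 estimates = estimates, ci = ci, ratios = ratios,
                 alpha = alpha, files = files))
}

#' Dot-plot of per-participant observed/expected ratios
#'
#' One jittered point per participant, panelled by gender or by exposure
#' group, with a vertical reference line at ratio = 1: points left of the
#' line sit below their expected level, points right of it above. The
#' jitter is seeded, so the layout is deterministic.
#'
#' @param ratios A [per_participant_ratios()] table.
#' @param outcome Outcome name to plot.
#' @param panel_by `"gender"` or `"group"`.
#' @param jitter_seed Seed for the vertical jitter.
#' @return A ggplot object.
#' @export
plot_ratios <- function(ratios, outcome, panel_by = "gender", jitter_seed = 1L) {
  stopifnot(panel_by %in% names(ratios))
  df <- ratios[ratios$outcome == outcome, , drop = FALSE]
  if (nrow(df) == 0L) stop(sprintf("no ratios for outcome '%s'", outcome), call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data[[panel_by]])) +
    ggplot2::geom_vline(xintercept = 1, linewidth = 0.6) +
    ggplot2::geom_point(
      position = ggplot2::position_jitter(width = 0, height = 0.25,
                                          seed = jitter_seed),
      alpha = 0.6, size = 1.6) +
    ggplot2::labs(
      x = "observed / expected score ratio",
      y = NULL,
      title = sprintf("Observed vs expected: %s by %s", outcome, panel_by)
    ) +
    ggplot2::theme_minimal(base_size = 11)
}
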