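# Draw an n x n_items ordinal response matrix from the latent-trait model.
# delta is the per-person latent mean (vector length n).
.generate_items <- function(n, definition, loading, delta, missing_rate) {
  tau <- .scale_thresholds(definition$name)
  trait <- stats::rnorm(n, mean = delta, sd = 1)
  noise_sd <- sqrt(1 - loading^2)
  m <- matrix(NA_integer_, n, definition$n_items)
  for (j in seq_len(definition$n_items)) {
    ystar <- loading * trait + stats::rnorm(n, 0, noise_sd)
    m[, j] <- definition$response_min + as.integer(rowSums(outer(ystar, tau, `>`)))
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n * definition$n_items) < missing_rate,
                   n, definition$n_items)
    m[drop] <- NA_integer_
  }
  colnames(m) <- item_columns(definition)
  m
}

.sample_ages <- function(n, range, weights) {
  ages <- seq.int(range[1L], range[2L])
  if (is.null(weights)) {
    sample(ages, n, replace = TRUE)
  } else {
    if (length(weights) != length(ages)) {
      stop("age weights must have one entry per age in the range", call. = FALSE)
    }
    sample(ages, n, replace = TRUE, prob = weights)
  }
}

#' Generate a synthetic reference-population table
#'
#' Ages are sampled uniformly on `reference_age_range` (or with the supplied
#' weights), gender is drawn with probability `gender_balance` of being
#' female, and item responses for both scales come from the latent-trait
#' ordinal model with zero latent shift — the reference population defines
#' the baseline. Missing responses are introduced completely at random at
#' `missing_rate` per item.
#'
#' All randomness derives from `config$seed` through a stream-splitting
#' scheme: the parent seed is used once to draw one child seed per table, so
#' [generate_reference()] and [generate_cohort()] are reproducible
#' independently of the order (or number of times) they are called.
#'
#' @param config A [synthetic_config()].
#' @param outcomes List of [scale_definition()]s to generate items for.
#' @return A tibble with `id`, `age`, `gender` and the item columns.
#' @export
generate_reference <- function(config, outcomes = list(hscl10(), css4())) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(.child_seeds(config$seed)$reference)
  n <- config$n_reference
  age <- .sample_ages(n, config$reference_age_range, config$age_weights_reference)
  gender <- ifelse(stats::runif(n) < config$gender_balance, "female", "male")
  out <- tibble::tibble(
    id = sprintf("ref_%05d", seq_len(n)),
    age = as.integer(age),
    gender = gender
  )
  for (def in outcomes) {
    loading <- .config_scalar(config$item_loading, def$name, "item_loading")
    items <- .generate_items(n, def, loading, delta = rep(0, n),
                             missing_rate = config$missing_rate)
    out <- dplyr::bind_cols(out, tibble::as_tibble(items))
  }
  out
}

#' Generate a synthetic exposed-cohort table
#'
#' As [generate_reference()], but each person also carries a `group` label
#' (`"survivor"` or `"bereaved"`, survivor with probability
#' `group_balance`), and the latent trait for each scale is shifted by
#' `latent_shift_cohort[scale]`, plus `latent_shift_group[scale]` for the
#' bereaved. With the default configuration this injects elevated distress
#' (more so among the bereaved) and reduced perceived support.
#'
#' @inheritParams generate_reference
#' @return A tibble with `id`, `age`, `gender`, `group` and the item columns.
#' @export
generate_cohort <- function(config, outcomes = list(hscl10(), css4())) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(.child_seeds(config$seed)$cohort)
  n <- config$n_cohort
  age <- .sample_ages(n, config$cohort_age_range, config$age_weights_cohort)
  gender <- ifelse(stats::runif(n) < config$gender_balance, "female", "male")
  group <- ifelse(stats::runif(n) < config$group_balance, "survivor", "bereaved")
  out <- tibble::tibble(
    id = sprintf("coh_%04d", seq_len(n)),
    age = as.integer(age),
    gender = gender,
    group = group
  )
  for (def in outcomes) {
    loading <- .config_scalar(config$item_loading, def$name, "item_loading")
    delta <- .config_scalar(config$latent_shift_cohort, def$name, "latent_shift_cohort") +
      (group == "bereaved") *
        .config_scalar(config$latent_shift_group, def$name, "latent_shift_group")
    items <- .generate_items(n, def, loading, delta = delta,
                             missing_rate = config$missing_rate)
    out <- dplyr::bind_cols(out, tibble::as_tibble(items))
  }
  out
}

# Per-scale entry from a scalar-or-named-vector config field.
.config_scalar <- function(x, name, what) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!name %in% names(x)) {
    stop(sprintf("`%s` has no entry for scale '%s'", what, name), call. = FALSE)
  }
  unname(x[[name]])
}

#' Write the synthetic tables as delimited text
#'
#' Writes `reference.csv` and `cohort.csv` (comma-separated, header row, one
#' row per person, missing items as empty fields) into `dir`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if absent).
#' @param outcomes List of [scale_definition()]s.
#' @return Invisibly, the two file paths.
#' @export
write_synthetic_tables <- function(config, dir,
                                   outcomes = list(hscl10(), css4())) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(reference = file.path(dir, "reference.csv"),
             cohort = file.path(dir, "cohort.csv"))
  readr::write_csv(generate_reference(config, outcomes), paths[["reference"]], na = "")
  readr::write_csv(generate_cohort(config, outcomes), paths[["cohort"]], na = "")
  invisible(paths)
}
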