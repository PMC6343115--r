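#' Configuration for the doubly-stratified bootstrap
#'
#' @param n_resamples Number of bootstrap resamples.
#' @param confidence_level Coverage level of the percentile intervals.
#' @param seed Integer seed. One parent seed deterministically yields one
#'   child seed per replicate, so the replicate set does not depend on the
#'   order of execution.
#' @param cohort_strata Columns defining the cohort resampling strata
#'   (default gender crossed with exposure group).
#' @param reference_strata Columns defining the reference resampling strata
#'   (default gender).
#' @param fallback_max_distance Age-distance horizon for empty-cell fallback
#'   when re-ascribing expected values inside a resample (see
#'   [ascribe_expected()]).
#' @param keep_replicates Keep the full replicate-by-estimand matrix as the
#'   `"replicates"` attribute of the result, for audit.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_resamples = 10000L,
                             confidence_level = 0.95,
                             seed = 1L,
                             cohort_strata = c("gender", "group"),
                             reference_strata = "gender",
                             fallback_max_distance = 5L,
                             keep_replicates = FALSE) {
  n_resamples <- as.integer(n_resamples)
  stopifnot(n_resamples >= 1L,
            confidence_level > 0, confidence_level < 1)
  structure(
    list(n_resamples = n_resamples,
         confidence_level = confidence_level,
         seed = as.integer(seed),
         cohort_strata = cohort_strata,
         reference_strata = reference_strata,
         fallback_max_distance = as.integer(fallback_max_distance),
         keep_replicates = isTRUE(keep_replicates)),
    class = "bootstrap_config"
  )
}

#' Bootstrap-percentile confidence interval
#'
#' Empirical quantiles of the replicate distribution at `(1 - level)/2` and
#' `1 - (1 - level)/2`, using linear interpolation of the empirical CDF
#' (quantile type 7). With all replicates equal the interval degenerates to
#' a point, which is legal.
#'
#' @param replicates Numeric vector of replicate estimates (at least two
#'   finite values).
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(low, high)`.
#' @export
percentile_ci <- function(replicates, level = 0.95) {
  x <- replicates[is.finite(replicates)]
  if (length(x) < 2L) {
    stop("percentile interval needs at least 2 finite replicates", call. = FALSE)
  }
  stopifnot(level > 0, level < 1)
  alpha <- (1 - level) / 2
  q <- stats::quantile(x, probs = c(alpha, 1 - alpha), type = 7, names = FALSE)
  c(low = q[1L], high = q[2L])
}

# ---- internal fast path -----------------------------------------------------

# Stratum membership as a list of row-index vectors, keyed by the sorted
# interaction of the stratum columns. Every stratum is non-empty by
# construction; resampling preserves each stratum's row count exactly.
.stratum_indices <- function(data, strata_cols) {
  missing_cols <- setdiff(strata_cols, names(data))
  if (length(missing_cols) > 0L) {
    stop(sprintf("stratum column '%s' is absent", missing_cols[1L]), call. = FALSE)
  }
  key <- do.call(paste, c(lapply(strata_cols, function(cl) data[[cl]]), sep = "\r"))
  split(seq_len(nrow(data)), key)
}

# Precompute everything the replicate loop needs as plain vectors/matrices.
.boot_prepare <- function(cohort, reference, outcomes, config) {
  genders <- sort(unique(reference$gender))
  bad <- setdiff(unique(cohort$gender), genders)
  if (length(bad) > 0L) {
    stop(sprintf("cohort gender '%s' has no reference stratum", bad[1L]),
         call. = FALSE)
  }
  amax <- max(reference$age, cohort$age)
  has_cut <- vapply(outcomes, function(d) !is.null(d$caseness_cutoff), logical(1))

  # reference base matrix: per outcome (value-with-NA-as-0, valid flag,
  # case flag where applicable), aggregated per replicate with one rowsum()
  cols <- list()
  for (k in seq_along(outcomes)) {
    def <- outcomes[[k]]
    s <- reference[[paste0(def$name, "_score")]]
    valid <- !is.na(s)
    cols[[length(cols) + 1L]] <- ifelse(valid, s, 0)
    cols[[length(cols) + 1L]] <- as.numeric(valid)
    if (has_cut[k]) {
      cs <- reference[[paste0(def$name, "_case")]]
      cols[[length(cols) + 1L]] <- as.numeric(valid & !is.na(cs) & cs)
    }
  }
  ref_base <- do.call(cbind, cols)
  offsets <- cumsum(c(0L, 2L + has_cut))[seq_along(outcomes)] # 0-based col offsets

  list(
    genders = genders,
    amax = amax,
    has_cut = has_cut,
    ref_base = ref_base,
    offsets = offsets,
    # flat cell index (age, gender) per reference row
    ref_cell = reference$age + (match(reference$gender, genders) - 1L) * amax,
    ref_strata = .stratum_indices(reference, config$reference_strata),
    coh_strata = .stratum_indices(cohort, config$cohort_strata),
    coh_age = as.integer(cohort$age),
    coh_gi = match(cohort$gender, genders),
    coh_obs = lapply(outcomes, function(d) cohort[[paste0(d$name, "_score")]]),
    coh_case = lapply(seq_along(outcomes), function(k) {
      if (has_cut[k]) as.numeric(cohort[[paste0(outcomes[[k]]$name, "_case")]])
      else NULL
    }),
    subgroups = .subgroup_masks(cohort)
  )
}

# Expected score / caseness per cohort participant from per-cell sums and
# counts (matrices age x gender), with symmetric pooled age fallback.
.expected_from_cells <- function(prep, cnt, ssum, csum, horizon) {
  n <- length(prep$coh_age)
  flat <- cbind(prep$coh_age, prep$coh_gi)
  c0 <- cnt[flat]
  e <- ssum[flat] / c0
  p <- if (is.null(csum)) NULL else csum[flat] / c0
  for (i in which(c0 == 0)) {
    a <- prep$coh_age[i]; gi <- prep$coh_gi[i]
    d <- 0L; tot <- 0
    while (tot == 0 && d < horizon) {
      d <- d + 1L
      nb <- c(a - d, a + d)
      nb <- nb[nb >= 1L & nb <= prep$amax]
      tot <- sum(cnt[nb, gi])
      if (tot > 0) {
        e[i] <- sum(ssum[nb, gi]) / tot
        if (!is.null(csum)) p[i] <- sum(csum[nb, gi]) / tot
      }
    }
    if (tot == 0) {
      e[i] <- NA_real_
      if (!is.null(csum)) p[i] <- NA_real_
    }
  }
  list(score = e, prop = p)
}

# One replicate: resample both samples within their strata, rebuild the
# expectation cells, and recompute every estimand for every subgroup.
# Returns a numeric vector aligned with .estimand_grid().
.boot_replicate <- function(prep, outcomes, horizon) {
  ridx <- unlist(lapply(prep$ref_strata, function(s)
    s[sample.int(length(s), length(s), replace = TRUE)]), use.names = FALSE)
  cidx <- unlist(lapply(prep$coh_strata, function(s)
    s[sample.int(length(s), length(s), replace = TRUE)]), use.names = FALSE)

  agg <- rowsum(prep$ref_base[ridx, , drop = FALSE], prep$ref_cell[ridx])
  cells <- as.integer(rownames(agg))
  ng <- length(prep$genders)

  out <- numeric(0)
  for (k in seq_along(outcomes)) {
    off <- prep$offsets[k]
    cnt <- matrix(0, prep$amax, ng)
    ssum <- matrix(0, prep$amax, ng)
    cnt[cells] <- agg[, off + 2L]
    ssum[cells] <- agg[, off + 1L]
    csum <- NULL
    if (prep$has_cut[k]) {
      csum <- matrix(0, prep$amax, ng)
      csum[cells] <- agg[, off + 3L]
    }
    ex <- .expected_from_cells(prep, cnt, ssum, csum, horizon)

    obs <- prep$coh_obs[[k]][cidx]
    evec <- ex$score[cidx]
    pvec <- if (is.null(ex$prop)) NULL else ex$prop[cidx]
    case <- if (is.null(prep$coh_case[[k]])) NULL else prep$coh_case[[k]][cidx]
    keep <- !is.na(obs)
    for (sg in names(prep$subgroups)) {
      km <- keep & prep$subgroups[[sg]][cidx]
      nk <- sum(km)
      vals <- rep(NA_real_, if (prep$has_cut[k]) 4L else 3L)
      if (nk >= 1L && !anyNA(evec[km]) && !any(evec[km] == 0)) {
        o <- obs[km]; e <- evec[km]
        om <- mean(o); em <- mean(e)
        sdo <- if (nk >= 2L) stats::sd(o) else NA_real_
        vals[1L] <- om - em
        vals[2L] <- om / em
        vals[3L] <- if (isTRUE(sdo > 0)) (om - em) / sdo else NA_real_
        if (prep$has_cut[k]) vals[4L] <- mean(case[km]) - mean(pvec[km])
      }
      out <- c(out, vals)
    }
  }
  out
}

.estimand_grid <- function(outcomes, subgroup_names) {
  rows <- list()
  for (k in seq_along(outcomes)) {
    def <- outcomes[[k]]
    ests <- c("mean_diff", "mean_ratio", "effect_size",
              if (!is.null(def$caseness_cutoff)) "prop_diff")
    for (sg in subgroup_names) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        outcome = def$name, subgroup = sg, estimand = ests)
    }
  }
  dplyr::bind_rows(rows)
}

#' Doubly-stratified bootstrap-percentile confidence intervals
#'
#' Attaches percentile confidence intervals to every comparison estimand
#' (mean difference, ratio of means, standardized effect size and — for
#' outcomes with a cut-off — excess caseness), overall and per subgroup.
#' In every resample, reference rows are drawn with replacement within each
#' reference stratum and cohort rows within each cohort stratum, both
#' preserving the original stratum sizes; the age-by-gender expectation
#' table is then rebuilt from the resampled reference and expected values
#' re-ascribed (with the empty-cell age fallback active) before the
#' estimands are recomputed. Reference-sample uncertainty therefore
#' propagates into the intervals.
#'
#' A replicate in which an estimand cannot be computed (for example, the
#' fallback horizon is exhausted for a participant in the subgroup) is
#' dropped for that estimand only and counted; `n_effective_resamples`
#' reports the replicates actually used. The reported `point` estimate is
#' always computed from the original samples, never the replicate mean.
#' Percentile intervals need not contain the point estimate in principle;
#' when one does not, a warning is logged but the interval stands.
#'
#' @param cohort Scored eligible cohort (see [score_responses()],
#'   [filter_eligible()]).
#' @param reference Scored reference sample.
#' @param outcomes List of [scale_definition()]s.
#' @param config A [bootstrap_config()].
#' @return A tibble with columns `outcome`, `subgroup`, `estimand`, `point`,
#'   `ci_low`, `ci_high`, `n_effective_resamples`. With
#'   `config$keep_replicates`, the replicate matrix (one column per estimand
#'   row) is attached as attribute `"replicates"`.
#' @export
run_bootstrap <- function(cohort, reference, outcomes = list(hscl10(), css4()),
                          config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  prep <- .boot_prepare(cohort, reference, outcomes, config)
  grid <- .estimand_grid(outcomes, names(prep$subgroups))
  B <- config$n_resamples

  # point estimates from the original samples
  stratum_table <- build_stratum_table(reference, outcomes)
  expected <- ascribe_expected(cohort, stratum_table,
                               fallback_max_distance = config$fallback_max_distance)
  point_tab <- compare(cohort, expected, outcomes)
  long <- tidyr::pivot_longer(
    point_tab[c("outcome", "subgroup", "mean_diff", "mean_ratio",
                "effect_size", "prop_diff")],
    cols = c("mean_diff", "mean_ratio", "effect_size", "prop_diff"),
    names_to = "estimand", values_to = "point")
  grid <- dplyr::left_join(grid, long, by = c("outcome", "subgroup", "estimand"))

  # per-replicate child seeds from the parent seed
  set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, B)

  reps <- matrix(NA_real_, B, nrow(grid))
  horizon <- config$fallback_max_distance
  for (b in seq_len(B)) {
    set.seed(child_seeds[b])
    reps[b, ] <- .boot_replicate(prep, outcomes, horizon)
  }

  n_eff <- colSums(!is.na(reps))
  ci <- t(vapply(seq_len(ncol(reps)), function(j) {
    x <- reps[!is.na(reps[, j]), j]
    if (length(x) < 2L) c(NA_real_, NA_real_) else percentile_ci(x, config$confidence_level)
  }, numeric(2L)))

  grid$ci_low <- ci[, 1L]
  grid$ci_high <- ci[, 2L]
  grid$n_effective_resamples <- as.integer(n_eff)

  dropped <- 1 - n_eff / B
  if (any(dropped > 0.01)) {
    worst <- which.max(dropped)
    warning(sprintf("%.1f%% of resamples dropped for estimand %s/%s/%s (and possibly others); interpret its interval with care",
                    100 * max(dropped), grid$outcome[worst], grid$subgroup[worst],
                    grid$estimand[worst]), call. = FALSE)
  }
  outside <- !is.na(grid$point) & !is.na(grid$ci_low) &
    (grid$point < grid$ci_low | grid$point > grid$ci_high)
  if (any(outside)) {
    warning(sprintf("percentile interval does not contain the point estimate for %d estimand(s); this is possible in principle but worth inspection",
                    sum(outside)), call. = FALSE)
  }
  if (config$keep_replicates) attr(grid, "replicates") <- reps
  grid
}
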