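test_that("percentile interval follows the type-7 quantile rule", {
  x <- as.numeric(1:100)
  ci <- percentile_ci(x, 0.95)
  # closed form for type 7 on 1..100: h = (n-1)p + 1
  expect_equal(unname(ci), c(1 + 99 * 0.025, 1 + 99 * 0.975), tolerance = 1e-12)

  expect_equal(unname(percentile_ci(rep(3.2, 10), 0.95)), c(3.2, 3.2))

  # narrowing the level collapses the interval toward the median
  wide <- percentile_ci(x, 0.95)
  mid <- percentile_ci(x, 0.5)
  tight <- percentile_ci(x, 0.01)
  expect_lt(mid[2] - mid[1], wide[2] - wide[1])
  expect_lt(tight[2] - tight[1], mid[2] - mid[1])
  expect_lt(abs(mean(tight) - stats::median(x)), 1)

  expect_error(percentile_ci(c(1), 0.95), "at least 2")
})

test_that("degenerate one-row strata force the identity resample", {
  coh <- scored_tbl(id = c("a", "b", "c"), gender = "male",
                    age = c(40, 40, 41), group = "survivor",
                    hscl = c(1.2, 1.9, 2.4), css = c(3, 4, 5))
  ref <- scored_tbl(id = paste0("r", 1:4), gender = "male", age = c(40, 40, 41, 41),
                    hscl = c(1.0, 1.4, 1.2, 1.6), css = c(4, 5, 4, 3))
  cfg <- bootstrap_config(n_resamples = 5, seed = 1, cohort_strata = "id",
                          reference_strata = "id", keep_replicates = TRUE)
  res <- run_bootstrap(coh, ref, config = cfg)
  reps <- attr(res, "replicates")
  for (j in seq_len(ncol(reps))) {
    expect_true(all(is.na(reps[, j])) || all(reps[, j] == reps[1, j]))
  }
  # every replicate equals the point estimate where both are defined
  defined <- !is.na(res$point) & !is.na(reps[1, ])
  expect_equal(reps[1, defined], res$point[defined], tolerance = 1e-12)
  expect_equal(unname(res$ci_low[defined]), unname(res$point[defined]),
               tolerance = 1e-12)
})

test_that("identical seed and config give identical results", {
  cfg_dat <- small_config(seed = 3)
  ref <- score_both(generate_reference(cfg_dat))
  coh <- score_both(generate_cohort(cfg_dat))
  b <- bootstrap_config(n_resamples = 60, seed = 11)
  r1 <- run_bootstrap(coh, ref, config = b)
  r2 <- run_bootstrap(coh, ref, config = b)
  expect_identical(r1, r2)
  r3 <- run_bootstrap(coh, ref, config = bootstrap_config(n_resamples = 60, seed = 12))
  expect_false(identical(r1$ci_low, r3$ci_low))
})

test_that("point estimates agree between compare() and the replicate path", {
  # with one-row strata the replicate path reproduces compare() exactly,
  # so the fast loop and the tidy path cannot drift apart
  cfg_dat <- synthetic_config(n_reference = 400L, n_cohort = 60L, seed = 21,
                              missing_rate = 0)
  ref <- score_both(generate_reference(cfg_dat))
  coh <- score_both(generate_cohort(cfg_dat))
  res <- run_bootstrap(coh, ref, config = bootstrap_config(
    n_resamples = 2, seed = 5, cohort_strata = "id", reference_strata = "id",
    keep_replicates = TRUE))
  reps <- attr(res, "replicates")
  defined <- !is.na(res$point) & !is.na(reps[1, ])
  expect_true(any(defined))
  expect_equal(reps[1, defined], res$point[defined], tolerance = 1e-12)
})

test_that("incomputable replicates are dropped per estimand and counted", {
  # one lone male reference row at age 74, the rest at age 20: resamples can
  # leave (male, 74) empty and beyond the 5-year fallback horizon of a
  # 74-year-old male participant
  ref <- scored_tbl(id = paste0("r", 1:6), gender = "male",
                    age = c(20, 20, 20, 20, 20, 74),
                    hscl = c(1.0, 1.2, 1.1, 1.3, 1.0, 1.5),
                    css = c(4, 4, 5, 4, 3, 4))
  coh <- scored_tbl(id = c("a", "b"), gender = "male", age = c(74, 74),
                    group = "survivor", hscl = c(2.0, 2.2), css = c(3, 3))
  expect_warning(
    res <- run_bootstrap(coh, ref, config = bootstrap_config(
      n_resamples = 200, seed = 2)),
    "dropped")
  expect_true(all(res$n_effective_resamples < 200))
  # P(cell (male,74) empty in a resample of 6) = (5/6)^6 ~ 0.33
  frac <- res$n_effective_resamples[1] / 200
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.85)
})

test_that("missing strata are rejected before iteration", {
  coh <- scored_tbl(id = "a", gender = "male", age = 40, group = "survivor",
                    hscl = 2, css = 3)
  ref <- scored_tbl(id = "r1", gender = "female", age = 40, hscl = 1.2, css = 4)
  expect_error(run_bootstrap(coh, ref), "no reference stratum")
  expect_error(run_bootstrap(coh[, setdiff(names(coh), "group")],
                             scored_tbl(id = "r1", gender = "male", age = 40,
                                        hscl = 1.2, css = 4)),
               "'group'")
})

test_that("interval width shrinks as samples grow", {
  widths <- vapply(c(50L, 200L, 800L), function(n) {
    cfg_dat <- synthetic_config(n_reference = 4L * n, n_cohort = n,
                                seed = 101L + n, missing_rate = 0)
    ref <- score_both(generate_reference(cfg_dat))
    coh <- score_both(generate_cohort(cfg_dat))
    res <- run_bootstrap(coh, ref, config = bootstrap_config(
      n_resamples = 300, seed = 6))
    i <- res$outcome == "hscl10" & res$subgroup == "total" &
      res$estimand == "mean_diff"
    res$ci_high[i] - res$ci_low[i]
  }, numeric(1))
  expect_true(widths[2] < widths[1] && widths[3] < widths[2])
})
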