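test_that("eligibility filter retains in-range ages and logs each exclusion", {
  # 165 in range, 19 over-age, 1 with undisclosed age
  cohort <- tibble::tibble(
    id = sprintf("p%03d", 1:185),
    age = c(sample(27:74, 165, replace = TRUE), sample(75:89, 19, replace = TRUE), NA)
  )
  res <- filter_eligible(cohort, c(18, 74))
  expect_equal(nrow(res$eligible), 165L)
  expect_equal(nrow(res$exclusions), 20L)
  expect_equal(sum(res$exclusions$reason == "over_age"), 19L)
  expect_equal(sum(res$exclusions$reason == "missing_age"), 1L)

  # all in range: identity
  all_in <- tibble::tibble(id = 1:5, age = c(18, 30, 50, 74, 60))
  res2 <- filter_eligible(all_in, c(18, 74))
  expect_equal(nrow(res2$eligible), 5L)
  expect_equal(nrow(res2$exclusions), 0L)

  # boundary: 17 against 18-74 is under-age
  res3 <- suppressWarnings(
    filter_eligible(tibble::tibble(id = "a", age = 17), c(18, 74)))
  expect_equal(res3$exclusions$reason, "under_age")
  expect_warning(filter_eligible(tibble::tibble(id = "a", age = 17), c(18, 74)),
                 "no cohort participants")
})

test_that("stratum table cells hold hand-computed statistics", {
  ref <- scored_tbl(id = paste0("r", 1:3), gender = rep("male", 3),
                    age = rep(57, 3), hscl = c(1.0, 1.3, 1.6))
  st <- build_stratum_table(ref, list(hscl10()))
  expect_equal(nrow(st), 1L)
  expect_equal(st$n, 3L)
  expect_equal(st$mean_score, 1.3)
  expect_equal(st$prop_case, 0)

  # inclusive cut-off inside the cell proportion
  ref2 <- scored_tbl(id = c("a", "b"), gender = "female", age = 40,
                     hscl = c(1.9, 1.0))
  st2 <- build_stratum_table(ref2, list(hscl10()))
  expect_equal(st2$prop_case, 0.5)

  # single-row reference
  st3 <- build_stratum_table(
    scored_tbl("x", "male", 30, hscl = 2.2), list(hscl10()))
  expect_equal(st3$mean_score, 2.2)
  expect_equal(st3$prop_case, 1)
})

test_that("stratum table is invariant to row order and drops rows per outcome", {
  set.seed(4)
  ref <- scored_tbl(id = paste0("r", 1:40),
                    gender = sample(c("male", "female"), 40, TRUE),
                    age = sample(30:33, 40, TRUE),
                    hscl = round(runif(40, 1, 3), 2),
                    css = round(runif(40, 1, 5), 2))
  ref$hscl10_score[c(3, 7)] <- NA  # unscored for distress only
  ref$hscl10_case[c(3, 7)] <- NA
  st <- build_stratum_table(ref)
  st_perm <- build_stratum_table(ref[sample(nrow(ref)), ])
  expect_identical(st, st_perm)
  # the two dropped rows still count for the support outcome
  expect_equal(sum(st$n[st$outcome == "css4"]), 40L)
  expect_equal(sum(st$n[st$outcome == "hscl10"]), 38L)
  expect_error(build_stratum_table(ref[, -which(names(ref) == "hscl10_score")],
                                   list(hscl10())), "hscl10_score")
})

test_that("expected values use exact cells, with pooled n-weighted fallback", {
  st <- build_stratum_table(
    scored_tbl(id = paste0("r", 1:6),
               gender = c(rep("male", 3), rep("female", 3)),
               age = c(57, 57, 57, 39, 39, 41),
               hscl = c(1.31, 1.31, 1.31, 1.0, 2.0, 2.6)),
    list(hscl10()))

  # direct lookup
  ex <- ascribe_expected(scored_tbl("p1", "male", 57, hscl = 1.6), st)
  expect_equal(ex$expected_score, 1.31)
  expect_equal(ex$fallback_distance, 0L)

  # (female, 40) missing; cells 39 (n=2, mean 1.5) and 41 (n=1, mean 2.6)
  # pool n-weighted: (2*1.5 + 1*2.6)/3
  ex2 <- ascribe_expected(scored_tbl("p2", "female", 40, hscl = 1.6), st)
  expect_equal(ex2$expected_score, (2 * 1.5 + 2.6) / 3)
  expect_equal(ex2$fallback_distance, 1L)

  # beyond the horizon: error naming the orphan participant
  expect_error(
    ascribe_expected(scored_tbl("p3", "female", 60, hscl = 1.6), st,
                     fallback_max_distance = 5),
    "p3")
  expect_error(ascribe_expected(scored_tbl("p4", "male", 57, hscl = 1), st[0, ]),
               "empty")
  expect_error(
    ascribe_expected(
      scored_tbl("p5", "nonbinary", 57, hscl = 1), st),
    "nonbinary")
})

test_that("mean expected caseness equals the cohort-weighted cell average", {
  cfg <- synthetic_config(n_reference = 3000L, n_cohort = 150L, seed = 13,
                          missing_rate = 0)
  ref <- score_both(generate_reference(cfg))
  coh <- score_both(generate_cohort(cfg))
  st <- build_stratum_table(ref)
  ex <- ascribe_expected(coh, st)
  exd <- ex[ex$outcome == "hscl10", ]
  # full reference covers every cohort cell: no fallback anywhere
  expect_true(all(ex$fallback_distance == 0L))
  # hand-weighted average of cell proportions with cohort weights
  std <- st[st$outcome == "hscl10", ]
  key <- paste(coh$gender, coh$age)
  manual <- std$prop_case[match(key, paste(std$gender, std$age))]
  expect_equal(mean(exd$expected_prop_case), mean(manual))
})
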