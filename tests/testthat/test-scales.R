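test_that("mean-of-valid-items scoring follows the missing-data rules", {
  # complete floor-of-scale vector
  s <- score_scale(rep(1, 10), hscl10())
  expect_equal(s$value, 1)
  expect_false(s$case)

  # one missing item allowed: mean of the nine others
  s <- score_scale(c(rep(2, 9), NA), hscl10())
  expect_equal(s$value, 2)
  expect_equal(s$n_valid, 9L)
  expect_true(s$case)

  # two missing on the 10-item scale: below min_valid_items, score absent
  s <- score_scale(c(rep(2, 8), NA, NA), hscl10())
  expect_true(is.na(s$value))
  expect_true(is.na(s$case))

  # support scale: 3 of 4 valid scores, 2 of 4 does not
  expect_equal(score_scale(c(4, 4, 4, NA), css4())$value, 4)
  expect_true(is.na(score_scale(c(4, 4, NA, NA), css4())$value))

  # hand-computed means straddling the cut-off
  v <- c(2, 2, 2, 2, 2, 1, 1, 1, 2, 2)
  expect_equal(score_scale(v, hscl10())$value, 1.7)
  expect_false(score_scale(v, hscl10())$case)
  v[6] <- 4
  expect_equal(score_scale(v, hscl10())$value, 2.0)
  expect_true(score_scale(v, hscl10())$case)
})

test_that("caseness comparison at the cut-off is inclusive", {
  # a reachable exact-cutoff value on a 2-item scale with integer responses
  def <- scale_definition("toy", "toy", 2, 1, 4, min_valid_items = 2,
                          caseness_cutoff = 2)
  expect_true(score_scale(c(2, 2), def)$case)   # exactly at the cut-off
  expect_false(score_scale(c(2, 1), def)$case)
  expect_true(score_scale(c(2, 3), def)$case)
})

test_that("invalid responses and wrong item counts are rejected with context", {
  expect_error(score_scale(c(rep(1, 9), 5), hscl10()), "item index 10")
  expect_error(score_scale(c(0, rep(1, 9)), hscl10()), "item index 1")
  expect_error(score_scale(c(1.5, rep(1, 9)), hscl10()), "integer")
  expect_error(score_scale(rep(1, 9), hscl10()), "expects 10 items, got 9")
})

test_that("scoring is order-invariant, exact on complete vectors, and monotone", {
  set.seed(11)
  for (rep in 1:25) {
    v <- sample(1:4, 10, replace = TRUE)
    miss <- sample(10, sample(0:1, 1))
    v[miss] <- NA
    s <- score_scale(v, hscl10())
    expect_equal(score_scale(sample(v), hscl10())$value, s$value)
    if (length(miss) == 0) expect_identical(s$value, mean(v))
    # raising one present response never lowers the score
    i <- sample(which(!is.na(v) & v < 4), 1)
    v2 <- v; v2[i] <- v2[i] + 1
    expect_gte(score_scale(v2, hscl10())$value, s$value)
  }
})

test_that("table-level scoring matches the per-person rule and names columns", {
  df <- tibble::tibble(
    hscl_1 = c(2, 2, 1), hscl_2 = c(2, NA, 1), hscl_3 = c(2, 2, 1),
    hscl_4 = c(2, 2, 1), hscl_5 = c(2, 2, 1), hscl_6 = c(2, 2, 1),
    hscl_7 = c(2, 2, 1), hscl_8 = c(2, 2, 1), hscl_9 = c(2, NA, 1),
    hscl_10 = c(2, 2, 1)
  )
  out <- score_responses(df, hscl10())
  expect_equal(out$hscl10_score, c(2, NA, 1))
  expect_equal(out$hscl10_n_valid, c(10L, 8L, 10L))
  expect_equal(out$hscl10_case, c(TRUE, NA, FALSE))
  expect_error(score_responses(df[-1], hscl10()), "hscl_1")
})

test_that("Cronbach's alpha matches a brute-force arithmetic oracle", {
  # 6 persons x 3 items; the oracle recomputes the formula from explicit
  # sums, independent of the implementation's code path
  m <- matrix(c(1, 2, 2,
                2, 3, 2,
                3, 3, 4,
                2, 1, 1,
                4, 4, 3,
                1, 2, 1), nrow = 6, byrow = TRUE)
  oracle <- function(m) {
    n <- nrow(m); k <- ncol(m)
    item_var <- numeric(k)
    for (j in 1:k) {
      mu <- sum(m[, j]) / n
      item_var[j] <- sum((m[, j] - mu)^2) / (n - 1)
    }
    tot <- m %*% rep(1, k)
    tot_var <- sum((tot - sum(tot) / n)^2) / (n - 1)
    k / (k - 1) * (1 - sum(item_var) / tot_var)
  }
  expect_equal(cronbach_alpha(m), oracle(m), tolerance = 1e-12)

  # perfect consistency: items are identical copies
  x <- c(1, 3, 2, 4, 2, 1)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)

  # two independent items: alpha ~ 0 (closed form with cov -> 0)
  set.seed(3)
  big <- cbind(rnorm(20000), rnorm(20000))
  expect_lt(abs(cronbach_alpha(big)), 0.05)
})

test_that("alpha preconditions are enforced", {
  expect_error(cronbach_alpha(matrix(1, 5, 1)), "at least 2 items")
  expect_error(cronbach_alpha(matrix(rnorm(4), 2, 2)), "at least 3 complete cases")
  expect_error(cronbach_alpha(matrix(1, 6, 3)), "variance is zero")
  # listwise deletion: NA rows are dropped before the precondition check
  m <- rbind(matrix(rnorm(12), 4, 3), c(NA, 1, 1))
  expect_silent(cronbach_alpha(m))
})
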