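trials_df <- function(digit, response, rt = 500) {
  data.frame(trial_index = seq_along(digit), digit = digit,
             onset_s = (seq_along(digit) - 1) * 3, response = response,
             rt_ms = rep_len(rt, length(digit)), stringsAsFactors = FALSE)
}

test_that("three-back scoring matches hand enumeration", {
  digits <- c(5, 2, 7, 5, 9, 7)
  correct_resp <- c("nonmatch", "nonmatch", "nonmatch",
                    "match", "nonmatch", "match")
  sc <- score_three_back(trials_df(digits, correct_resp))
  expect_equal(sc$truth[4:6], c("match", "nonmatch", "match"))
  expect_equal(which(sc$scorable), 4:6)
  expect_equal(accuracy(sc), 1)
  inverted <- ifelse(correct_resp == "match", "nonmatch", "match")
  expect_equal(accuracy(score_three_back(trials_df(digits, inverted))), 0)
  expect_error(score_three_back(trials_df(c(1, 2, 3), rep("match", 3))),
               "at least 4")
  expect_error(score_three_back(trials_df(digits, rep("yes", 6))),
               "malformed")
})

test_that("three-back scorer agrees with brute-force enumeration", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    digit <- sample(0:9, n, replace = TRUE)
    response <- sample(c("match", "nonmatch", "none"), n, replace = TRUE,
                       prob = c(0.3, 0.6, 0.1))
    got <- score_three_back(trials_df(digit, response))$correct
    expect_identical(got, oracle_three_back(digit, response))
  }
})

test_that("zero-back scoring is parity judgment", {
  sc <- score_zero_back(trials_df(c(4, 7), c("even", "even")))
  expect_equal(sc$correct, c(TRUE, FALSE))
  set.seed(14)
  digit <- sample(0:9, 200, replace = TRUE)
  resp <- ifelse(digit %% 2 == 0, "even", "odd")
  expect_equal(accuracy(score_zero_back(trials_df(digit, resp))), 1)
})

test_that("omission policy is explicit", {
  digit <- c(2, 4, 6, 8)
  resp <- c("even", "even", "none", "even")
  sc <- score_zero_back(trials_df(digit, resp))
  expect_equal(accuracy(sc, "incorrect"), 3 / 4)
  expect_equal(accuracy(sc, "exclude"), 1)
})

test_that("rt indices use the declared quantile rule", {
  tr <- trials_df(c(2, 4, 6, 8), rep("even", 4), rt = c(400, 500, 600, 700))
  out <- rt_indices(tr, min_n = 4)
  expect_equal(out$mean_rt_ms, 550)
  expect_equal(out$rt_iqr_ms, 150)    # type-7: Q3 625 - Q1 475
  tr2 <- trials_df(rep(2, 10), rep("even", 10), rt = 500)
  expect_equal(rt_indices(tr2)$rt_iqr_ms, 0)
  expect_error(rt_indices(trials_df(2, "even")), "responded")
  # correct and incorrect contribute alike
  tr3 <- trials_df(c(2, 3, 4, 5, 6, 7, 8, 9),
                   c("even", "even", "even", "even",
                     "even", "odd", "even", "odd"), rt = 600)
  expect_equal(rt_indices(tr3)$mean_rt_ms, 600)
})

test_that("IQR shifts and scales as an interval measure", {
  set.seed(15)
  rt <- runif(50, 300, 900)
  tr <- function(r) trials_df(rep(2, 50), rep("even", 50), rt = r)
  base <- rt_indices(tr(rt))$rt_iqr_ms
  expect_equal(rt_indices(tr(rt + 123))$rt_iqr_ms, base, tolerance = 1e-9)
  expect_equal(rt_indices(tr(rt * 2.5))$rt_iqr_ms, 2.5 * base,
               tolerance = 1e-9)
})

test_that("rt fluctuation index isolates the very-low-frequency band", {
  n <- 200
  t <- (seq_len(n) - 1) * 3
  mk <- function(rt) trials_df(rep(2, n), rep("even", n), rt = rt)
  flat <- rt_fluctuation_spectrum(mk(rep(600, n)))
  expect_lt(flat$rt_fluct_index, 1e-12)
  slow <- rt_fluctuation_spectrum(mk(600 + 100 * sin(2 * pi * 0.02 * t)))
  fast <- rt_fluctuation_spectrum(mk(600 + 100 * sin(2 * pi * 0.1 * t)))
  expect_gte(slow$rt_fluct_index / fast$rt_fluct_index, 10)
  # offset invariance
  set.seed(16)
  rt <- 600 + rnorm(n, 0, 50)
  expect_equal(rt_fluctuation_spectrum(mk(rt))$rt_fluct_index,
               rt_fluctuation_spectrum(mk(rt + 500))$rt_fluct_index,
               tolerance = 1e-9)
  # 200 trials at 3-s ISI span 600 s: grid finer than 0.005 Hz
  expect_lt(min(diff(slow$freq)), 0.005)
  # missing-response budget
  tr <- mk(rep(600, n)); tr$response[1:60] <- "none"
  expect_error(rt_fluctuation_spectrum(tr), "missing")
})

test_that("summarize_behavior assembles all indices", {
  run <- synth_behavior(condition = "three_back", accuracy_true = 0.85,
                        rt_drift_amp_ms = 80, seed = 17)
  s <- summarize_behavior(run)
  expect_equal(s$condition, "three_back")
  expect_true(s$accuracy > 0.6 && s$accuracy < 1)
  expect_true(s$rt_iqr_ms > 0 && s$rt_fluct_index > 0)
  expect_equal(s$n_responded, 200)
})
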