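test_that("generators are deterministic in the seed", {
  expect_identical(synth_eeg(duration_s = 5, seed = 30)$samples,
                   synth_eeg(duration_s = 5, seed = 30)$samples)
  expect_false(identical(synth_eeg(duration_s = 5, seed = 30)$samples,
                         synth_eeg(duration_s = 5, seed = 31)$samples))
  p1 <- synth_ppg(duration_s = 31, seed = 30)
  p2 <- synth_ppg(duration_s = 31, seed = 30)
  expect_identical(p1$recording$samples, p2$recording$samples)
  expect_identical(p1$beat_times_s, p2$beat_times_s)
  expect_identical(synth_behavior(seed = 30)$trials,
                   synth_behavior(seed = 30)$trials)
  # generators restore the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(synth_eeg(duration_s = 2, seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generator contracts reject impossible parameters", {
  expect_error(synth_eeg(modulation_depth = 1.2), "\\[0, 1\\]")
  expect_error(synth_ppg(rsa_amp_ms = 500), "mean_ibi_ms / 2")
  expect_error(synth_ppg(mean_ibi_ms = 300), "\\[500, 1500\\]")
  expect_error(cohort_spec(n_participants = 2), ">= 4")
  expect_error(cohort_spec(trait_rho = 1.5), "trait_rho")
})

test_that("synthetic EEG band composition is visible to the bandpower stage", {
  fr <- vapply(c(2, 5, 12), function(a) {
    eeg <- synth_eeg(duration_s = 40, alpha_amp = a, modulation_depth = 0,
                     seed = 32)
    rec <- bandpass(remove_offset(eeg), filter_spec())
    mean(first_order_series(rec)$values)
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("scored accuracy is an unbiased image of accuracy_true", {
  set.seed(33)
  accs <- vapply(1:200, function(i) {
    run <- synth_behavior(condition = "three_back", accuracy_true = 0.8,
                          seed = 4000 + i)
    accuracy(score_three_back(run))
  }, numeric(1))
  expect_equal(mean(accs), 0.8, tolerance = 0.01)
})

test_that("RT drift raises the fluctuation index", {
  gain <- vapply(1:8, function(s) {
    drift <- synth_behavior(condition = "three_back", rt_drift_amp_ms = 100,
                            rt_drift_period_s = 50, seed = 500 + s)
    none <- synth_behavior(condition = "three_back", rt_drift_amp_ms = 0,
                           seed = 500 + s)
    rt_fluctuation_spectrum(drift)$rt_fluct_index >
      rt_fluctuation_spectrum(none)$rt_fluct_index
  }, logical(1))
  expect_gte(mean(gain), 7 / 8)
})

test_that("cohorts carry coupled ground truth and are reproducible", {
  sp <- cohort_spec(n_participants = 6, trait_rho = 0.7, seed = 34)
  co <- synth_cohort(sp, modalities = c("behavior"))
  expect_length(co$sessions, 6)
  expect_equal(nrow(co$ground_truth), 12)
  expect_setequal(unique(co$ground_truth$condition),
                  c("zero_back", "three_back"))
  co2 <- synth_cohort(sp, modalities = c("behavior"))
  expect_identical(co$ground_truth, co2$ground_truth)
  expect_identical(co$sessions$P01$three_back$trials$trials,
                   co2$sessions$P01$three_back$trials$trials)
  # three-back depth spans its configured range, zero-back is fixed
  gt3 <- co$ground_truth[co$ground_truth$condition == "three_back", ]
  gt0 <- co$ground_truth[co$ground_truth$condition == "zero_back", ]
  expect_true(all(gt3$modulation_depth >= sp$depth_three_range[1] &
                  gt3$modulation_depth <= sp$depth_three_range[2]))
  expect_true(all(gt0$modulation_depth == sp$depth_zero))
})

test_that("latent coupling induces the target parameter-level correlation", {
  sp <- cohort_spec(n_participants = 200, trait_rho = 0.7, seed = 35)
  co <- synth_cohort(sp, modalities = "behavior")
  gt <- co$ground_truth[co$ground_truth$condition == "three_back", ]
  expect_equal(cor(gt$modulation_depth, gt$accuracy_true), 0.68,
               tolerance = 0.08)
})
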