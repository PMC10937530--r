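fake_series <- function(n, n_ch = 6, seed = 1) {
  set.seed(seed)
  cogload:::new_power_series(matrix(runif(n * n_ch), ncol = n_ch),
                             band_def("alpha"), fs_series = 1, t0_s = 60,
                             channel_labels = eeg_channels()[1:n_ch])
}

test_that("feature assembly yields 24 aligned dimensions", {
  a1 <- fake_series(341, seed = 1); t1 <- fake_series(341, seed = 2)
  a2 <- second_order_series(a1); t2 <- second_order_series(t1)
  X <- build_features(a1, t1, a2, t2)
  expect_equal(dim(X), c(212, 24))
  # trailing alignment: first feature row pairs first-order sample 130
  expect_equal(unname(X[1, 1:6]), unname(a1$values[130, ]))
  expect_equal(attr(X, "time_s")[1], 60 + 129)
  bad <- fake_series(341, n_ch = 5, seed = 3)
  expect_error(build_features(bad, t1, a2, t2), "6-channel")
})

test_that("z-normalization standardizes within scope and is idempotent", {
  set.seed(18)
  X <- matrix(rnorm(200 * 4, mean = 5, sd = 3), ncol = 4)
  groups <- rep(c("a", "b"), each = 100)
  Z <- z_normalize(X, groups)
  for (g in c("a", "b")) {
    expect_true(all(abs(colMeans(Z[groups == g, ])) < 1e-9))
    expect_true(all(abs(apply(Z[groups == g, ], 2, sd) - 1) < 1e-9))
  }
  expect_equal(z_normalize(Z, groups), Z, tolerance = 1e-9)
  # constant dimension flagged and zeroed
  X[, 2] <- 7
  expect_warning(Z2 <- z_normalize(X), "zero-variance")
  expect_true(all(Z2[, 2] == 0))
})

test_that("LOPO folds partition by participant and the harness learns", {
  d <- synth_arousal_features(n_participants = 6, n_per_state = 30,
                              separation_sd = 4, seed = 19)
  Z <- z_normalize(d$X, d$participants)
  m <- train_lopo(Z, d$labels, d$participants)
  for (id in names(m$folds))
    expect_true(all(d$participants[m$folds[[id]]] == id))
  expect_gte(m$mean_accuracy, 0.9)
  expect_error(train_lopo(Z[1:60, ], d$labels[1:60], d$participants[1:60]),
               ">= 3 participants")
  # single-class training fold
  lab_bad <- d$labels
  lab_bad[d$participants != "P1"] <- "low"
  expect_error(train_lopo(Z, lab_bad, d$participants), "single class")
})

test_that("accuracy grows with cluster separation", {
  accs <- vapply(c(1, 2, 4), function(sep) {
    d <- synth_arousal_features(n_participants = 5, n_per_state = 25,
                                separation_sd = sep, seed = 20)
    train_lopo(z_normalize(d$X, d$participants), d$labels,
               d$participants)$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("trace estimation saturates correctly and recovers mixtures", {
  d <- synth_arousal_features(n_participants = 5, n_per_state = 40,
                              separation_sd = 6, seed = 21)
  Z <- z_normalize(d$X, d$participants)
  m <- train_lopo(Z, d$labels, d$participants)
  hi <- estimate_trace(m, Z[d$labels == "high", ])
  lo <- estimate_trace(m, Z[d$labels == "low", ])
  expect_gte(hi$high_portion, 0.97)
  expect_lte(lo$high_portion, 0.03)
  # 70% high-state mixture recovered within 0.1
  set.seed(22)
  portions <- vapply(1:5, function(i) {
    pick <- c(sample(which(d$labels == "high"), 140),
              sample(which(d$labels == "low"), 60))
    estimate_trace(m, Z[pick, ])$high_portion
  }, numeric(1))
  expect_true(all(abs(portions - 0.7) <= 0.1))
  # decision invariant to vector order
  perm <- sample(nrow(Z))
  expect_equal(estimate_trace(m, Z[perm, ])$decisions[order(perm)],
               estimate_trace(m, Z)$decisions, ignore_attr = TRUE)
  expect_error(estimate_trace(m, Z[, 1:10]), "dimension")
})
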