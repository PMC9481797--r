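test_that("majority voting implements the at-least-4-of-7 rule", {
  expect_equal(majority_vote(rep(0, 7)), 0L)
  expect_equal(majority_vote(rep(1, 7)), 1L)
  expect_equal(majority_vote(c(1, 1, 1, 1, 0, 0, 0)), 1L)
  expect_equal(majority_vote(c(1, 1, 1, 0, 0, 0, 0)), 0L)
  expect_error(majority_vote(c(0, 1)), "even")
  expect_equal(majority_vote(c(0, 1), threshold = 1), 1L)
  expect_error(majority_vote(integer(0)), "empty")
  expect_error(majority_vote(c(0, 2, 1)), "binary")
})

test_that("grouped splits never divide a group and are seed-reproducible", {
  cfg <- tiny_config(seed = 40)
  ts <- sample_trials(cfg)$trials
  for (seed in 1:20) {
    sp <- grouped_split(ts, 0.15, seed = seed)
    expect_length(intersect(unique(sp$train$group), unique(sp$test$group)), 0)
    expect_equal(length(sp$train) + length(sp$test), length(ts))
  }
  s1 <- grouped_split(ts, 0.15, seed = 9)
  s2 <- grouped_split(ts, 0.15, seed = 9)
  expect_identical(s1$test$trial_id, s2$test$trial_id)

  one_group <- subset_trials(ts, ts$group == "G1")
  expect_error(grouped_split(one_group), "2 distinct groups")
})

test_that("the 6-groups-of-3 design holds out exactly one group at 15%", {
  cfg <- synth_config(S = 4L, fs = 200, trial_seconds = c(1.2, 1.4),
                      n_subjects = 1L, n_groups = 6L, views_per_group = 3L,
                      seed = 41)
  ts <- sample_trials(cfg)$trials
  sp <- grouped_split(ts, 0.15, seed = 2)
  expect_length(unique(sp$test$group), 1)
  expect_equal(length(sp$test), 3)
})

test_that("fitting learns the informative band and is deterministic", {
  cfg <- tiny_config(seed = 42)
  ts <- sample_trials(cfg)$trials
  dcfg <- fast_config() # theta, beta2, gamma
  model <- decoder_fit(ts, dcfg)
  pred <- decoder_predict(model, ts)
  # training accuracy per band: beta2 carries the class signal, theta none
  acc <- vapply(c("theta", "beta2"), function(b) mean(pred[[b]] == ts$label),
                numeric(1))
  expect_gt(acc["beta2"], 0.9)
  expect_lt(acc["theta"], 0.85)

  model2 <- decoder_fit(ts, dcfg)
  expect_equal(model$band_models$beta2$classifier$w,
               model2$band_models$beta2$classifier$w)
  expect_equal(names(model$band_models$beta2$subject_means$mean),
               c("S1", "S2"))
})

test_that("prediction is self-consistent on re-presented training trials", {
  cfg <- tiny_config(seed = 43)
  ts <- sample_trials(cfg)$trials
  dcfg <- fast_config()
  model <- decoder_fit(ts, dcfg)
  p1 <- decoder_predict(model, ts)
  p2 <- decoder_predict(model, subset_trials(ts, 1:4))
  expect_equal(p1$label[1:4], p2$label)
  expect_equal(p1$beta2[1:4], p2$beta2)
})

test_that("held-out ensemble accuracy is high when the signal is strong", {
  cfg <- tiny_config(seed = 44)
  ts <- sample_trials(cfg)$trials
  sp <- grouped_split(ts, 0.25, seed = 3)
  model <- decoder_fit(sp$train, fast_config())
  pred <- decoder_predict(model, sp$test)
  expect_gte(mean(pred$label == sp$test$label), 0.75)
})

test_that("strict subject mode rejects unseen subjects at prediction time", {
  cfg <- tiny_config(seed = 45)
  ts <- sample_trials(cfg)$trials
  train <- subset_trials(ts, ts$subject == "S1")
  test <- subset_trials(ts, ts$subject == "S2")
  model <- decoder_fit(train, fast_config())
  expect_error(decoder_predict(model, test), "S2")
  lenient <- decoder_fit(train, fast_config(strict_subjects = FALSE))
  expect_s3_class(decoder_predict(lenient, test), "data.frame")
})

test_that("test-group trials never influence their own predictions (no leakage)", {
  cfg <- tiny_config(seed = 46)
  ts <- sample_trials(cfg)$trials
  sp <- grouped_split(ts, 0.25, seed = 4)
  dcfg <- fast_config()
  model <- decoder_fit(sp$train, dcfg)
  pred1 <- decoder_predict(model, sp$test)
  # refit after shuffling the labels of a held-out group: identical output
  ts2 <- ts
  flip <- ts2$group %in% unique(sp$test$group)
  ts2$label[flip] <- 1L - ts2$label[flip]
  sp2 <- list(train = subset_trials(ts2, !flip), test = subset_trials(ts2, flip))
  expect_identical(decoder_predict(decoder_fit(sp2$train, dcfg), sp2$test)$label,
                   pred1$label)
})

test_that("evaluation reports calibrated accuracies over repeated splits", {
  cfg <- tiny_config(seed = 47)
  ts <- sample_trials(cfg)$trials
  rep <- decoder_evaluate(ts, n_repeats = 5, test_fraction = 0.25, seed = 10,
                          config = fast_config())
  expect_length(rep$accuracies, 5)
  expect_true(rep$mean_accuracy >= 0 && rep$mean_accuracy <= 1)
  expect_named(rep$band_accuracy, c("theta", "beta2", "gamma"))
  expect_gte(rep$band_accuracy[["beta2"]], 0.7)
})

test_that("alignment improves decoding when subject shift dominates", {
  # subject congruence shift large relative to the class effect: without
  # recentering, between-subject displacement swamps the class structure
  cfg <- synth_config(S = 4L, fs = 200, trial_seconds = c(1.5, 2),
                      n_subjects = 3L, n_groups = 6L, views_per_group = 3L,
                      informative_bands = "beta2", effect_size = 1,
                      subject_shift_scale = 2, seed = 77)
  samp <- sample_trials(cfg)
  d <- vapply(seq_len(50), function(s) {
    sp <- grouped_split(samp$trials, 0.15, seed = 3000 + s)
    vapply(c(TRUE, FALSE), function(al) {
      m <- decoder_fit(sp$train, fast_config(align = al))
      mean(decoder_predict(m, sp$test)$label == sp$test$label)
    }, numeric(1))
  }, numeric(2))
  expect_gt(median(d[1, ] - d[2, ]), 0)
})

test_that("ensemble models survive a save/load round trip", {
  cfg <- tiny_config(seed = 48)
  ts <- sample_trials(cfg)$trials
  model <- decoder_fit(ts, fast_config())
  dir <- withr::local_tempdir()
  save_ensemble(model, dir)
  back <- load_ensemble(dir)
  p1 <- decoder_predict(model, ts)
  p2 <- decoder_predict(back, ts)
  expect_equal(p1$label, p2$label)
  expect_equal(p1$beta2, p2$beta2)
})

test_that("baselines behave like their definitions", {
  cfg <- tiny_config(seed = 49)
  ts <- sample_trials(cfg)$trials
  sp <- grouped_split(ts, 0.25, seed = 5)
  # 1-NN on a re-presented training trial returns its own label
  pred_self <- baseline_rknn(sp$train, sp$train, k = 1)
  expect_equal(pred_self, sp$train$label)
  expect_error(baseline_rknn(sp$train, sp$test, k = 100), "exceeds")

  # agreement with brute-force nearest neighbour on the aligned wideband SCMs
  pb <- riemeeg:::prepare_baseline(sp$train, sp$test, c(1, 45),
                                   decoder_config())
  brute <- vapply(pb$test, function(C) {
    dv <- vapply(pb$train, airm_distance, numeric(1), C1 = C)
    sp$train$label[which.min(dv)]
  }, integer(1))
  expect_equal(baseline_rknn(sp$train, sp$test, k = 1), brute)

  # tangent vectors have length S(S+1)/2 and preserve the AIRM norm
  C <- rand_spd_fixture(4, seed = 50)
  ref <- rand_spd_fixture(4, seed = 51)
  v <- tangent_vector(C, riemeeg:::spd_invsqrt(ref))
  expect_length(v, 4 * 5 / 2)
  expect_equal(sqrt(sum(v^2)), airm_distance(ref, C), tolerance = 1e-8)

  pred_t <- baseline_tangent_svm(sp$train, sp$test)
  expect_true(all(pred_t %in% c(0L, 1L)))
  expect_length(pred_t, length(sp$test))
})
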