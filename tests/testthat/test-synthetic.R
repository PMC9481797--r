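test_that("class covariances are SPD and separate monotonically in effect size", {
  gaps <- vapply(c(0, 0.5, 1, 2), function(e) {
    cfg <- synth_config(effect_size = e, seed = 30)
    covs <- make_class_covariances(cfg)
    for (cv in covs) {
      expect_true(is_spd(cv$class0))
      expect_true(is_spd(cv$class1))
    }
    airm_distance(covs$beta2$class0, covs$beta2$class1)
  }, numeric(1))
  expect_equal(gaps[1], 0)
  expect_true(all(diff(gaps) > 0))

  cfg0 <- synth_config(effect_size = 0, seed = 30)
  covs0 <- make_class_covariances(cfg0)
  expect_identical(covs0$gamma$class0, covs0$gamma$class1)
  # non-informative bands always share the class covariance
  cfg <- synth_config(effect_size = 2, seed = 30)
  covs <- make_class_covariances(cfg)
  expect_identical(covs$theta$class0, covs$theta$class1)
})

test_that("sampled trials are reproducible and carry the configured design", {
  cfg <- tiny_config(seed = 31)
  s1 <- sample_trials(cfg)
  s2 <- sample_trials(cfg)
  expect_identical(s1$trials$trials, s2$trials$trials)
  expect_identical(s1$trials$label, s2$trials$label)

  ts <- s1$trials
  expect_equal(length(ts), cfg$n_subjects * cfg$n_groups * cfg$views_per_group)
  expect_equal(sort(unique(ts$subject)), c("S1", "S2"))
  expect_equal(length(unique(ts$group)), cfg$n_groups)
  # per-subject balanced labels, constant within (subject, group)
  for (s in unique(ts$subject)) {
    expect_equal(sum(ts$label[ts$subject == s]),
                 cfg$n_groups / 2 * cfg$views_per_group)
    for (g in unique(ts$group))
      expect_length(unique(ts$label[ts$subject == s & ts$group == g]), 1)
  }
  lens <- vapply(ts$trials, ncol, integer(1))
  expect_true(all(lens >= cfg$trial_seconds[1] * cfg$fs - 1 &
                    lens <= cfg$trial_seconds[2] * cfg$fs + 1))
})

test_that("a long single-band trial reproduces its generating covariance", {
  cfg <- synth_config(S = 4L, fs = 200, trial_seconds = c(60, 60),
                      n_subjects = 1L, n_groups = 2L, views_per_group = 1L,
                      informative_bands = "beta2", effect_size = 0,
                      subject_shift_scale = 0, seed = 32)
  covs <- make_class_covariances(cfg)
  samp <- sample_trials(cfg)
  X <- bandpass(samp$trials$trials[[1]], standard_bands()[6, ], cfg$fs)
  C <- estimate_scm(X)
  # band-pass filtering scales total power by the in-band fraction; compare
  # shapes after trace normalisation
  w <- 1 / sqrt((20 + 30) / 2)
  target <- w^2 * covs$beta2$class0
  Cn <- C / sum(diag(C)); Tn <- target / sum(diag(target))
  expect_lt(norm(Cn - Tn, "F") / norm(Tn, "F"), 0.1)
})

test_that("subject congruence shifts are removed by alignment by >= 10x", {
  cfg <- synth_config(S = 4L, fs = 200, trial_seconds = c(4, 5),
                      n_subjects = 2L, n_groups = 4L, views_per_group = 3L,
                      informative_bands = character(0), effect_size = 0,
                      subject_shift_scale = 0.5, seed = 33)
  samp <- sample_trials(cfg)
  fts <- bandpass_set(samp$trials, c(1, 45))
  scms <- lapply(fts$trials, estimate_scm)
  sm <- fit_subject_means(scms, fts$subject)
  pre <- airm_distance(sm$mean$S1, sm$mean$S2)
  aligned <- align_set(scms, fts$subject, sm)
  post <- airm_distance(karcher_mean(aligned[fts$subject == "S1"]),
                        karcher_mean(aligned[fts$subject == "S2"]))
  expect_gt(pre / post, 10)
})

test_that("ww-scores are calibrated at null effect and powerful at effect 2", {
  # null: identical class covariances => embedded ww-score centred near 0
  base <- rand_spd_fixture(4, seed = 60)
  null_scores <- vapply(seq_len(100), function(r) {
    cloud <- sample_scm_cloud(10, list(base, base), dispersion = 0.05,
                              seed = 6000 + r)
    X <- embed_training(fit_mds(pairwise_airm(cloud$scms)))
    ww_test(X, cloud$labels, n_permutations = 100, seed = r)$ww_score
  }, numeric(1))
  expect_lt(abs(mean(null_scores)), 0.3)

  # power: one informative band at effect size 2 separates the classes
  cfg <- synth_config(informative_bands = "beta2", effect_size = 2, seed = 61)
  covs <- make_class_covariances(cfg)
  strong <- vapply(seq_len(50), function(r) {
    cloud <- sample_scm_cloud(12, list(covs$beta2$class0, covs$beta2$class1),
                              dispersion = 0.02, seed = 7000 + r)
    X <- embed_training(fit_mds(pairwise_airm(cloud$scms)))
    ww_test(X, cloud$labels, n_permutations = 100, seed = r)$ww_score
  }, numeric(1))
  expect_gte(mean(strong < -2), 0.9)
})

test_that("SCM clouds recover their generators and stay balanced", {
  S <- 4
  gen <- list(rand_spd_fixture(S, seed = 34), rand_spd_fixture(S, seed = 35))
  cloud <- sample_scm_cloud(40, gen, dispersion = 0.02, seed = 36)
  expect_equal(sum(cloud$labels == 0), 40)
  expect_equal(sum(cloud$labels == 1), 40)
  expect_true(all(vapply(cloud$scms, is_spd, logical(1))))
  m0 <- karcher_mean(cloud$scms[cloud$labels == 0])
  expect_lt(airm_distance(m0, gen[[1]]), 0.35)
  expect_error(sample_scm_cloud(5, gen, dispersion = 0), "positive")
})
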