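#' @title Synthetic two-class multi-subject EEG generator
#' @description Seeded generator of band-structured EEG trials and SCM
#'   clouds with known ground truth, emulating the statistical structure the
#'   decoder is built for: class-conditional spatial covariance differences
#'   confined to chosen frequency bands, and per-subject covariate shift
#'   realised as a random congruence of the sensor space. Congruence shifts
#'   (rather than additive offsets) are used because Riemannian alignment
#'   removes exactly congruence effects, making the alignment-benefit check
#'   a true positive control.
#' @name synthetic
NULL

#' Configuration for the synthetic generator
#'
#' Defaults mirror the study design the decoder targets: 8 sensors at
#' 500 Hz, 2 subjects, 6 stimulus groups of 3 views each (each subject views
#' every group; half of each subject's groups are labelled "buy"), trial
#' lengths uniform in 1.5-2.5 s, class covariance separation (`effect_size`)
#' 2 confined to the beta2 and gamma bands, and subject congruence shifts of
#' scale 0.5.
#'
#' @param S sensor count.
#' @param fs sampling rate in Hz.
#' @param trial_seconds length-2 range of trial durations (s).
#' @param n_subjects number of subjects.
#' @param n_groups stimulus groups per subject.
#' @param views_per_group repeated presentations per group.
#' @param informative_bands names (see [standard_bands()]) of bands whose
#'   class covariances differ.
#' @param effect_size log-spectral gap between class covariances in the
#'   informative bands; 0 means identically distributed classes.
#' @param subject_shift_scale magnitude of each subject's random congruence;
#'   0 means no covariate shift.
#' @param seed integer seed; everything downstream is reproducible from it.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(S = 8L, fs = 500, trial_seconds = c(1.5, 2.5),
                         n_subjects = 2L, n_groups = 6L, views_per_group = 3L,
                         informative_bands = c("beta2", "gamma"),
                         effect_size = 2, subject_shift_scale = 0.5,
                         seed = 1L) {
  bands <- standard_bands()
  if (!all(informative_bands %in% bands$name))
    stop_invalid("unknown band name(s): ",
                 paste(setdiff(informative_bands, bands$name), collapse = ", "))
  if (effect_size < 0 || subject_shift_scale < 0)
    stop_invalid("effect_size and subject_shift_scale must be >= 0")
  if (fs <= 2 * max(bands$high_hz))
    stop_invalid("fs must exceed twice the highest band edge")
  structure(list(
    S = as.integer(S), fs = fs, trial_seconds = trial_seconds,
    n_subjects = as.integer(n_subjects), n_groups = as.integer(n_groups),
    views_per_group = as.integer(views_per_group),
    informative_bands = informative_bands, effect_size = effect_size,
    subject_shift_scale = subject_shift_scale, seed = as.integer(seed)
  ), class = "synth_config")
}

## random symmetric generator with unit Frobenius norm
rand_sym_unit <- function(S) {
  G <- matrix(stats::rnorm(S * S), S)
  G <- symmetrize(G)
  G / norm(G, "F")
}

## well-conditioned random SPD via a Wishart draw with generous df
rand_spd <- function(S, df = 4L * S) {
  W <- stats::rWishart(1, df, diag(S) / df)[, , 1]
  symmetrize(W)
}

#' Per-band, per-class ground-truth covariances
#'
#' Draws a base SPD covariance per band from a seeded Wishart construction;
#' in each informative band the class-1 covariance is \eqn{W \Sigma W'} with
#' \eqn{W = \mathrm{expm}(e \cdot G)} for a fixed random unit-norm symmetric
#' generator G and effect size e, so the AIRM gap between the classes grows
#' monotonically with e. Non-informative bands share one covariance across
#' classes.
#'
#' @param config a `synth_config`.
#' @return named list over bands; each element a list with SPD `class0`,
#'   `class1` and the band edges.
#' @export
make_class_covariances <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  bands <- standard_bands()
  with_seed(config$seed, {
    G <- rand_sym_unit(config$S)
    out <- lapply(seq_len(nrow(bands)), function(b) {
      Sigma <- rand_spd(config$S)
      if (bands$name[b] %in% config$informative_bands) {
        W <- sym_expm(config$effect_size * G)
        list(class0 = Sigma, class1 = symmetrize(W %*% Sigma %*% W),
             low_hz = bands$low_hz[b], high_hz = bands$high_hz[b])
      } else {
        list(class0 = Sigma, class1 = Sigma,
             low_hz = bands$low_hz[b], high_hz = bands$high_hz[b])
      }
    })
    names(out) <- bands$name
    out
  })
}

#' Sample a synthetic multi-subject trial set
#'
#' Each trial is a sum over the seven bands of band-limited Gaussian
#' processes: white noise spatially coloured by the square root of the
#' class/band covariance, band-pass filtered, weighted by a mild 1/sqrt(f)
#' spectral tilt, then mapped through the subject's congruence transform
#' \eqn{A_s = \mathrm{expm}(s \cdot G_s)}. Labels are assigned per
#' (subject, group): each subject's groups are split half and half between
#' the classes. Fully reproducible from the config seed.
#'
#' @param config a `synth_config`.
#' @return list with `trials` (a `trial_set`) and `truth` (class
#'   covariances, per-subject transforms, per-subject group labels, config).
#' @export
sample_trials <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  covs <- make_class_covariances(config)
  bands <- standard_bands()
  chol_l <- lapply(covs, function(cv)
    list(t(chol(cv$class0)), t(chol(cv$class1))))
  w_band <- 1 / sqrt((bands$low_hz + bands$high_hz) / 2)
  with_seed(config$seed + 1L, {
    subjects <- paste0("S", seq_len(config$n_subjects))
    A <- lapply(subjects, function(s)
      sym_expm(config$subject_shift_scale * rand_sym_unit(config$S)))
    names(A) <- subjects
    # per-subject class assignment of groups, balanced
    group_labels <- lapply(subjects, function(s) {
      l <- rep(c(1L, 0L), length.out = config$n_groups)
      sample(l)
    })
    names(group_labels) <- subjects
    trials <- list(); label <- integer(0); subject <- character(0)
    group <- character(0)
    for (s in subjects) for (g in seq_len(config$n_groups)) {
      y <- group_labels[[s]][g]
      for (v in seq_len(config$views_per_group)) {
        Tn <- round(stats::runif(1, config$trial_seconds[1],
                                 config$trial_seconds[2]) * config$fs)
        X <- matrix(0, config$S, Tn)
        for (b in seq_len(nrow(bands))) {
          L <- chol_l[[b]][[y + 1]]
          noise <- matrix(stats::rnorm(config$S * Tn), config$S)
          X <- X + w_band[b] *
            bandpass(L %*% noise, bands[b, ], config$fs)
        }
        trials[[length(trials) + 1]] <- A[[s]] %*% X
        label <- c(label, y)
        subject <- c(subject, s)
        group <- c(group, paste0("G", g))
      }
    }
    list(trials = trial_set(trials, label, subject, group, config$fs),
         truth = list(class_covariances = covs, subject_transforms = A,
                      group_labels = group_labels, config = config))
  })
}

#' Sample a labelled SPD cloud around two class covariances
#'
#' Wishart draws around each class covariance, bypassing time-series
#' synthesis; used to exercise alignment, embedding and classification in
#' isolation. `dispersion` is approximately the reciprocal of the Wishart
#' degrees of freedom: larger values scatter the draws more widely.
#'
#' @param n_per_class draws per class.
#' @param class_covariances list of two SPD matrices (class 0, class 1).
#' @param dispersion positive scatter parameter (default 0.05).
#' @param seed RNG seed.
#' @return list with `scms` (list of SPD matrices) and `labels` (0/1).
#' @export
sample_scm_cloud <- function(n_per_class, class_covariances,
                             dispersion = 0.05, seed = 1L) {
  if (dispersion <= 0) stop_invalid("dispersion must be positive")
  S <- nrow(class_covariances[[1]])
  df <- max(S + 2, round(1 / dispersion))
  with_seed(seed, {
    draws <- lapply(1:2, function(k) {
      arr <- stats::rWishart(n_per_class, df, class_covariances[[k]] / df)
      lapply(seq_len(n_per_class), function(i) symmetrize(arr[, , i]))
    })
    list(scms = c(draws[[1]], draws[[2]]),
         labels = rep(c(0L, 1L), each = n_per_class))
  })
}
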