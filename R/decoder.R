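#' @title Seven-band Riemannian ensemble decoder
#' @description The full preference decoder: for each of the seven analysis
#'   bands, band-pass the trials, estimate spatial covariances, recentre
#'   them per subject on the SPD manifold, embed the inter-trial AIRM
#'   distances by classical MDS, and train a linear max-margin classifier on
#'   the embedded coordinates. An unseen trial is filtered, aligned with its
#'   subject's stored mean, placed into each band's embedding by the
#'   out-of-sample extension, and classified; the ensemble label is decided
#'   by majority voting (at least 4 of the 7 band classifiers).
#' @name decoder
NULL

#' Decoder configuration
#'
#' @param bands data.frame of analysis bands (default [standard_bands()]).
#' @param cost soft-margin cost C of the linear SVMs (default 1).
#' @param balanced_weights weight classes by inverse frequency in the SVMs
#'   (default `TRUE`); grouped splits remove whole stimuli and therefore
#'   unbalance the training labels, which otherwise biases every band
#'   classifier toward the majority class.
#' @param d MDS dimension per band, or `"auto"`.
#' @param vote_threshold votes required for class 1 (default majority,
#'   `ceiling((n_bands + 1) / 2)`).
#' @param align per-subject Riemannian alignment on/off (default on;
#'   switching it off quantifies the covariate-shift penalty).
#' @param strict_subjects reject test trials from subjects unseen at
#'   training time (`TRUE`, default) or align them by the global training
#'   mean (`FALSE`).
#' @param karcher_tol,karcher_max_iter Frechet-mean solver settings.
#' @param ridge_factor SCM eigenvalue floor (see [estimate_scm()]).
#' @return a list of class `decoder_config`.
#' @export
decoder_config <- function(bands = standard_bands(), cost = 1,
                           balanced_weights = TRUE, d = "auto",
                           vote_threshold = NULL, align = TRUE,
                           strict_subjects = TRUE, karcher_tol = 1e-9,
                           karcher_max_iter = 200L, ridge_factor = 1e-10) {
  nb <- nrow(bands)
  if (is.null(vote_threshold)) {
    if (nb %% 2 == 0)
      stop_invalid("even band count requires an explicit vote_threshold")
    vote_threshold <- (nb + 1) %/% 2
  }
  structure(list(bands = bands, cost = cost,
                 balanced_weights = balanced_weights, d = d,
                 vote_threshold = as.integer(vote_threshold), align = align,
                 strict_subjects = strict_subjects, karcher_tol = karcher_tol,
                 karcher_max_iter = karcher_max_iter,
                 ridge_factor = ridge_factor),
            class = "decoder_config")
}

## extract (weights, bias, positive class) from a linear e1071 SVM so the
## decision rule is a plain dot product everywhere (memory and disk paths).
## Inverse-frequency class weights counteract the structural label imbalance
## that grouped splits induce (holding out a whole stimulus removes one
## class's trials disproportionately).
linear_svm_fit <- function(coords, y, cost, balanced = TRUE) {
  yf <- factor(y, levels = c(0, 1))
  cw <- if (balanced) {
    tab <- table(yf)
    stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  } else c("0" = 1, "1" = 1)
  fit <- e1071::svm(coords, yf, kernel = "linear", cost = cost,
                    class.weights = cw,
                    scale = FALSE, type = "C-classification")
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  pred <- as.integer(as.character(stats::predict(fit, coords)))
  dec <- as.numeric(coords %*% w + b)
  # calibrate the sign convention against libsvm's own predictions
  agree <- mean((dec > 0) == (pred == 1))
  if (agree < 0.5) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

fit_band_model <- function(train, band, config) {
  fts <- bandpass_set(train, band)
  scms <- lapply(fts$trials, estimate_scm, ridge_factor = config$ridge_factor)
  if (config$align) {
    sm <- fit_subject_means(scms, fts$subject, tol = config$karcher_tol,
                            max_iter = config$karcher_max_iter)
    aligned <- align_set(scms, fts$subject, sm)
  } else {
    sm <- NULL
    aligned <- scms
  }
  D <- pairwise_airm(aligned, ids = fts$trial_id)
  emb <- fit_mds(D, d = config$d)
  coords <- embed_training(emb)
  svm <- linear_svm_fit(coords, fts$label, config$cost,
                        balanced = config$balanced_weights)
  structure(list(band = band, subject_means = sm, embedding = emb,
                 train_scms = aligned, classifier = svm),
            class = "band_model")
}

#' Fit the ensemble decoder
#'
#' @param train a `trial_set` with at least two trials per class.
#' @param config a `decoder_config` (default settings if omitted).
#' @return an object of class `ensemble_model`.
#' @export
decoder_fit <- function(train, config = decoder_config()) {
  stopifnot(inherits(train, "trial_set"))
  if (length(unique(train$label)) < 2 || any(table(train$label) < 2))
    stop_invalid("need at least 2 training trials per class")
  if (train$fs <= 2 * max(config$bands$high_hz))
    stop_invalid("highest band edge is not below fs/2")
  band_models <- lapply(seq_len(nrow(config$bands)), function(b)
    fit_band_model(train, config$bands[b, ], config))
  names(band_models) <- config$bands$name
  structure(list(band_models = band_models, config = config,
                 classes = c(0L, 1L)),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(
    "<ensemble_model> %d band classifiers (vote threshold %d), alignment %s\n",
    length(x$band_models), x$config$vote_threshold,
    if (x$config$align) "on" else "off"))
  invisible(x)
}

#' Majority vote over binary band decisions
#'
#' Returns 1 when at least `threshold` of the votes are 1 (with the default
#' seven bands: at least 4 of 7), else 0.
#'
#' @param votes vector of 0/1 votes.
#' @param threshold votes required for class 1; defaults to a strict
#'   majority and errors on an even vote count without an explicit value.
#' @return a single 0/1 label.
#' @export
majority_vote <- function(votes, threshold = NULL) {
  if (length(votes) == 0) stop_invalid("empty vote list")
  if (!all(votes %in% c(0, 1))) stop_invalid("votes must be binary")
  if (is.null(threshold)) {
    if (length(votes) %% 2 == 0)
      stop_invalid("even vote count requires an explicit threshold")
    threshold <- (length(votes) + 1) %/% 2
  }
  as.integer(sum(votes) >= threshold)
}

predict_band <- function(bm, test, config) {
  fts <- bandpass_set(test, bm$band)
  scms <- lapply(fts$trials, estimate_scm, ridge_factor = config$ridge_factor)
  aligned <- if (config$align)
    align_set(scms, fts$subject, bm$subject_means,
              strict = config$strict_subjects)
  else scms
  vapply(aligned, function(C) {
    dvec <- vapply(bm$train_scms, airm_distance, numeric(1), C1 = C)
    x <- embed_oos(bm$embedding, dvec)
    as.integer(sum(x * bm$classifier$w) + bm$classifier$b > 0)
  }, integer(1))
}

#' Predict labels for unseen trials
#'
#' @param model an `ensemble_model` from [decoder_fit()].
#' @param test a `trial_set`; under strict subject mode every test subject
#'   must have been present at training time.
#' @return a data.frame with `trial_id`, one 0/1 vote column per band, and
#'   the majority-vote `label`.
#' @export
decoder_predict <- function(model, test) {
  stopifnot(inherits(model, "ensemble_model"), inherits(test, "trial_set"))
  if (model$config$align && model$config$strict_subjects) {
    known <- names(model$band_models[[1]]$subject_means$mean)
    unknown <- setdiff(unique(test$subject), known)
    if (length(unknown) > 0)
      stop_invalid("test subject(s) unseen at training time: ",
                   paste(unknown, collapse = ", "))
  }
  votes <- vapply(model$band_models, predict_band,
                  integer(length(test$trials)), test = test,
                  config = model$config)
  votes <- matrix(votes, nrow = length(test$trials),
                  dimnames = list(NULL, names(model$band_models)))
  out <- data.frame(trial_id = test$trial_id, votes, check.names = FALSE)
  out$label <- apply(votes, 1, majority_vote,
                     threshold = model$config$vote_threshold)
  out
}

#' Grouped train/test split
#'
#' Partitions whole groups (stimuli/products), never single trials, so that
#' all views of one stimulus land on the same side. The number of held-out
#' groups is chosen to bring the realised test-trial fraction closest to
#' `test_fraction`, with at least one group on each side.
#'
#' @param ts a `trial_set` with at least 2 distinct groups.
#' @param test_fraction target fraction of trials in the test set
#'   (default 0.15).
#' @param seed RNG seed; identical seeds give identical splits.
#' @return list with `train` and `test` trial sets.
#' @export
grouped_split <- function(ts, test_fraction = 0.15, seed = 1L) {
  stopifnot(inherits(ts, "trial_set"))
  groups <- unique(ts$group)
  if (length(groups) < 2) stop_invalid("need at least 2 distinct groups")
  perm <- with_seed(seed, sample(groups))
  sizes <- vapply(perm, function(g) sum(ts$group == g), integer(1))
  cum <- cumsum(sizes)
  n <- length(ts$trials)
  k <- which.min(abs(cum[seq_len(length(groups) - 1)] / n - test_fraction))
  test_groups <- perm[seq_len(k)]
  idx <- ts$group %in% test_groups
  list(train = subset_trials(ts, !idx), test = subset_trials(ts, idx))
}

#' Repeated grouped-split evaluation
#'
#' Repeats the grouped 85/15 split, refits the full decoder on each training
#' portion (subject means included, so nothing leaks across the split), and
#' reports mean and standard deviation of the held-out accuracy, overall and
#' per band. Splits whose training portion lacks a class are resampled and
#' counted.
#'
#' @param ts a `trial_set`.
#' @param n_repeats number of splits (default 100).
#' @param test_fraction target held-out trial fraction (default 0.15).
#' @param seed base seed; split i uses `seed + i`.
#' @param config a `decoder_config`.
#' @return an object of class `evaluation_report`: `accuracies` (length
#'   `n_repeats`), `mean_accuracy`, `sd_accuracy`, `band_accuracy` (named
#'   means), `n_resampled`, and the split descriptor.
#' @export
decoder_evaluate <- function(ts, n_repeats = 100L, test_fraction = 0.15,
                             seed = 1L, config = decoder_config()) {
  stopifnot(inherits(ts, "trial_set"))
  accs <- numeric(n_repeats)
  band_hits <- NULL; band_n <- 0
  n_resampled <- 0L
  offset <- 0L
  for (i in seq_len(n_repeats)) {
    repeat {
      sp <- grouped_split(ts, test_fraction, seed = seed + i + offset)
      ok <- length(unique(sp$train$label)) == 2 &&
        all(table(factor(sp$train$label, levels = c(0, 1))) >= 2)
      if (ok) break
      n_resampled <- n_resampled + 1L
      offset <- offset + n_repeats
    }
    model <- decoder_fit(sp$train, config)
    pred <- decoder_predict(model, sp$test)
    accs[i] <- mean(pred$label == sp$test$label)
    vb <- as.matrix(pred[, config$bands$name, drop = FALSE])
    hits <- colSums(vb == sp$test$label)
    band_hits <- if (is.null(band_hits)) hits else band_hits + hits
    band_n <- band_n + length(sp$test$label)
  }
  structure(list(
    accuracies = accs,
    mean_accuracy = mean(accs),
    sd_accuracy = stats::sd(accs),
    band_accuracy = band_hits / band_n,
    n_resampled = n_resampled,
    split = list(test_fraction = test_fraction, n_repeats = n_repeats,
                 seed = seed)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> accuracy %.3f +/- %.3f over %d grouped splits (test fraction %g)\n",
    x$mean_accuracy, x$sd_accuracy, x$split$n_repeats, x$split$test_fraction))
  cat("per-band accuracy:",
      paste(sprintf("%s %.2f", names(x$band_accuracy), x$band_accuracy),
            collapse = ", "), "\n")
  invisible(x)
}
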