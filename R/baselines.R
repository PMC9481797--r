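#' @title Riemannian baseline classifiers
#' @description The two standard covariance-based comparators: Riemannian
#'   k-nearest neighbours (geodesic distances fed to a plain kNN rule) and
#'   the tangent-space SVM (SCMs mapped to the Euclidean tangent space at
#'   the training barycenter and classified by a linear SVM). Both operate
#'   on per-subject aligned wideband SCMs, mirroring the ensemble decoder's
#'   preprocessing so comparisons are like for like.
#' @name baselines
NULL

baseline_scms <- function(ts, band, config) {
  fts <- bandpass_set(ts, band)
  lapply(fts$trials, estimate_scm, ridge_factor = config$ridge_factor)
}

prepare_baseline <- function(train, test, band, config) {
  scms_tr <- baseline_scms(train, band, config)
  scms_te <- baseline_scms(test, band, config)
  if (config$align) {
    sm <- fit_subject_means(scms_tr, train$subject, tol = config$karcher_tol,
                            max_iter = config$karcher_max_iter)
    scms_tr <- align_set(scms_tr, train$subject, sm)
    scms_te <- align_set(scms_te, test$subject, sm,
                         strict = config$strict_subjects)
  }
  list(train = scms_tr, test = scms_te)
}

#' Riemannian k-nearest-neighbour baseline
#'
#' Classifies each test SCM by the majority label of its k AIRM-nearest
#' training SCMs (distance-ordered tie-break toward the nearer neighbour's
#' label on an even split).
#'
#' @param train,test `trial_set`s.
#' @param k neighbour count (default 5); must not exceed the training size.
#' @param band analysis band (default wideband 1-45 Hz).
#' @param config a `decoder_config` (alignment and SCM settings are reused).
#' @return integer vector of 0/1 predicted labels for `test`.
#' @export
baseline_rknn <- function(train, test, k = 5L, band = c(1, 45),
                          config = decoder_config()) {
  stopifnot(inherits(train, "trial_set"), inherits(test, "trial_set"))
  if (k > length(train$trials))
    stop_invalid("k exceeds the number of training trials")
  pb <- prepare_baseline(train, test, band, config)
  vapply(pb$test, function(C) {
    dvec <- vapply(pb$train, airm_distance, numeric(1), C1 = C)
    nn <- order(dvec)[seq_len(k)]
    votes <- train$label[nn]
    if (sum(votes == 1) != sum(votes == 0))
      as.integer(sum(votes == 1) > sum(votes == 0))
    else votes[1] # tie: nearest neighbour decides
  }, integer(1))
}

#' Map an SPD matrix to the tangent space at a reference point
#'
#' Vectorises \eqn{\mathrm{logm}(B^{-1/2} C B^{-1/2})} as its upper triangle
#' with off-diagonal entries weighted by \eqn{\sqrt{2}}, so the Euclidean
#' norm of the vector equals the AIRM distance of C to the reference. The
#' result has length S(S+1)/2.
#'
#' @param C SPD matrix.
#' @param ref_invsqrt the reference point's inverse square root.
#' @return numeric vector of length S(S+1)/2.
#' @export
tangent_vector <- function(C, ref_invsqrt) {
  L <- spd_logm(symmetrize(ref_invsqrt %*% C %*% ref_invsqrt))
  ut <- upper.tri(L)
  c(diag(L), sqrt(2) * L[ut])
}

#' Tangent-space SVM baseline
#'
#' Projects the aligned SCMs onto the tangent space at the Frechet mean of
#' the training SCMs and trains a linear SVM on the resulting
#' S(S+1)/2-dimensional vectors.
#'
#' @inheritParams baseline_rknn
#' @return integer vector of 0/1 predicted labels for `test`.
#' @export
baseline_tangent_svm <- function(train, test, band = c(1, 45),
                                 config = decoder_config()) {
  stopifnot(inherits(train, "trial_set"), inherits(test, "trial_set"))
  pb <- prepare_baseline(train, test, band, config)
  bary <- karcher_mean(pb$train, tol = config$karcher_tol,
                       max_iter = config$karcher_max_iter)
  Wb <- spd_invsqrt(bary)
  Xtr <- t(vapply(pb$train, tangent_vector, numeric(nrow(bary) * (nrow(bary) + 1) / 2),
                  ref_invsqrt = Wb))
  Xte <- t(vapply(pb$test, tangent_vector, numeric(ncol(Xtr)),
                  ref_invsqrt = Wb))
  svm <- linear_svm_fit(Xtr, train$label, config$cost,
                        balanced = config$balanced_weights)
  as.integer(Xte %*% svm$w + svm$b > 0)
}
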