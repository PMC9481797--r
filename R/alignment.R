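#' @title Per-subject Riemannian alignment
#' @description Covariance descriptors of different subjects (or recording
#'   sessions) typically form similarly shaped clouds centred at different
#'   points of the SPD manifold — a covariate shift. Recentering each
#'   subject's SCMs around the identity by the congruence
#'   \eqn{C^A = \bar{B}^{-1/2} C \bar{B}^{-1/2}}, with \eqn{\bar{B}} that
#'   subject's training-set Frechet mean, removes exactly this shift while
#'   preserving all within-subject AIRM distances (congruences are
#'   isometries).
#' @name alignment
NULL

#' Fit per-subject Frechet means for alignment
#'
#' Computes, for each distinct subject id, the Karcher mean of that subject's
#' SCMs and caches its inverse square root. Means are fitted on training data
#' only; test-time trials are aligned with the stored means (never refitted),
#' so no information leaks from test trials.
#'
#' @param scms list of SPD matrices.
#' @param subject_ids character/factor vector, one id per SCM.
#' @param tol,max_iter passed to [karcher_mean()].
#' @return an object of class `subject_means`: named lists `mean` and
#'   `invsqrt`, plus the pooled mean of the per-subject means under
#'   `global_mean` (used in lenient mode for unseen subjects).
#' @export
fit_subject_means <- function(scms, subject_ids, tol = 1e-9, max_iter = 200L) {
  if (length(scms) != length(subject_ids))
    stop_invalid("scms and subject_ids differ in length")
  if (anyNA(subject_ids)) stop_invalid("missing subject id")
  subject_ids <- as.character(subject_ids)
  subs <- sort(unique(subject_ids))
  means <- lapply(subs, function(s)
    karcher_mean(scms[subject_ids == s], tol = tol, max_iter = max_iter))
  names(means) <- subs
  structure(list(
    mean = means,
    invsqrt = lapply(means, spd_invsqrt),
    global_mean = karcher_mean(means, tol = tol, max_iter = max_iter)
  ), class = "subject_means")
}

#' @export
print.subject_means <- function(x, ...) {
  cat(sprintf("<subject_means> %d subject(s): %s\n",
              length(x$mean), paste(names(x$mean), collapse = ", ")))
  invisible(x)
}

#' Align an SCM by a reference Frechet mean
#'
#' Applies the recentering congruence \eqn{\bar{B}^{-1/2} C \bar{B}^{-1/2}}.
#' Aligning a subject's own mean yields the identity matrix.
#'
#' @param C SPD matrix to align.
#' @param mean the reference SPD mean \eqn{\bar{B}}.
#' @return the aligned SPD matrix.
#' @export
align_scm <- function(C, mean) {
  assert_spd(C, "C"); assert_spd(mean, "mean")
  if (!all(dim(C) == dim(mean))) stop_invalid("C and mean differ in size")
  W <- spd_invsqrt(mean)
  symmetrize(W %*% C %*% W)
}

#' Align a set of SCMs by their subjects' stored means
#'
#' @param scms list of SPD matrices.
#' @param subject_ids one subject id per SCM.
#' @param means a `subject_means` object from [fit_subject_means()].
#' @param strict if `TRUE` (default), an SCM from a subject without a stored
#'   mean is an error; if `FALSE`, such SCMs are aligned by the global mean.
#' @return list of aligned SPD matrices.
#' @export
align_set <- function(scms, subject_ids, means, strict = TRUE) {
  stopifnot(inherits(means, "subject_means"))
  subject_ids <- as.character(subject_ids)
  unknown <- setdiff(unique(subject_ids), names(means$mean))
  if (length(unknown) > 0 && strict)
    stop_invalid("unknown subject(s): ", paste(unknown, collapse = ", "))
  W_global <- if (length(unknown) > 0) spd_invsqrt(means$global_mean)
  mapply(function(C, s) {
    W <- if (s %in% names(means$invsqrt)) means$invsqrt[[s]] else W_global
    symmetrize(W %*% C %*% W)
  }, scms, subject_ids, SIMPLIFY = FALSE)
}
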