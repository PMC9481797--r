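#' @title Frequency-band filterbank
#' @description Zero-phase Butterworth filtering of EEG trials into the seven
#'   classical analysis bands (delta through gamma), the 0.5-45 Hz wideband
#'   preprocessing filter, and the short-trial exclusion rule. Filters are
#'   3rd-order Butterworth designs applied forward-backward (zero phase lag;
#'   6th-order magnitude response) with odd-reflection padding at the edges
#'   to suppress transients.
#' @name filterbank
NULL

#' The seven standard EEG analysis bands
#'
#' delta 1-4, theta 4-8, alpha1 8-10, alpha2 10-13, beta1 13-20, beta2 20-30
#' and gamma 30-45 Hz. The 8 Hz boundary belongs to both theta and alpha1;
#' bands are filtered independently, so edge overlap is harmless.
#'
#' @return a data.frame with columns `name`, `low_hz`, `high_hz` (7 rows).
#' @export
standard_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2", "gamma"),
    low_hz = c(1, 4, 8, 10, 13, 20, 30),
    high_hz = c(4, 8, 10, 13, 20, 30, 45),
    stringsAsFactors = FALSE)
}

## forward-backward filtering of one channel with odd-reflection padding
## (3x filter length at each edge, the usual filtfilt convention)
filtfilt_refl <- function(b, a, x) {
  npad <- 3L * max(length(a), length(b))
  n <- length(x)
  if (n <= npad)
    stop_invalid(sprintf(
      "signal too short for stable zero-phase filtering: need > %d samples, got %d",
      npad, n))
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(npad + 1):(npad + n)]
}

butter_design <- function(low_hz, high_hz, fs, order = 3L) {
  nyq <- fs / 2
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < nyq))
    stop_invalid(sprintf(
      "band [%g, %g] Hz not filterable at fs = %g Hz (need 0 < low < high < fs/2)",
      low_hz, high_hz, fs))
  signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
}

#' Band-pass filter a trial (zero phase)
#'
#' Applies a 3rd-order Butterworth band-pass forward and backward to every
#' channel. Output has the same shape as the input and zero phase lag.
#'
#' @param X sensors x samples matrix.
#' @param band a one-row data.frame with `low_hz`, `high_hz` (e.g. one row of
#'   [standard_bands()]), or a numeric `c(low, high)` pair.
#' @param fs sampling rate in Hz.
#' @return the filtered matrix.
#' @export
bandpass <- function(X, band, fs) {
  if (is.numeric(band)) band <- data.frame(low_hz = band[1], high_hz = band[2])
  bt <- butter_design(band$low_hz[1], band$high_hz[1], fs)
  if (!is.matrix(X)) stop_invalid("trial must be a matrix (sensors x samples)")
  out <- t(apply(X, 1, function(ch) filtfilt_refl(bt$b, bt$a, ch)))
  dimnames(out) <- dimnames(X)
  out
}

#' Wideband preprocessing filter (0.5-45 Hz)
#'
#' The zero-phase 3rd-order Butterworth band-pass applied to continuous
#' recordings before artifact cleaning and trial segmentation.
#'
#' @inheritParams bandpass
#' @return the filtered matrix.
#' @export
wideband_filter <- function(X, fs) bandpass(X, c(0.5, 45), fs)

#' Band-pass filter every trial of a trial set
#'
#' @param ts a `trial_set`.
#' @param band as in [bandpass()].
#' @return a `trial_set` with filtered trials, metadata unchanged.
#' @export
bandpass_set <- function(ts, band) {
  stopifnot(inherits(ts, "trial_set"))
  out <- ts
  out$trials <- lapply(ts$trials, bandpass, band = band, fs = ts$fs)
  out
}

#' Remove trials shorter than a minimum duration
#'
#' Trials shorter than `min_seconds` carry too few samples to express the
#' slowest analysis band (delta needs at least one 1 Hz cycle) and are
#' dropped; trials of exactly the minimum length are retained. Metadata
#' pairing and order are preserved.
#'
#' @param ts a `trial_set`.
#' @param min_seconds minimum trial duration in seconds (default 1).
#' @return the filtered `trial_set`; a warning is emitted if nothing remains.
#' @export
exclude_short_trials <- function(ts, min_seconds = 1.0) {
  stopifnot(inherits(ts, "trial_set"))
  keep <- vapply(ts$trials, ncol, integer(1)) >= min_seconds * ts$fs
  if (!any(keep)) {
    warning("all trials shorter than the minimum duration; empty trial set")
    out <- ts
    out$trials <- list(); out$label <- integer(0); out$subject <- character(0)
    out$group <- character(0); out$trial_id <- character(0)
    return(out)
  }
  subset_trials(ts, keep)
}
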