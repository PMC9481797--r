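#' @title Wavelet-ICA artifact cleaning
#' @description Semi-automated suppression of ocular/muscular/cardiac
#'   artifacts in continuous EEG: split the recording into non-overlapping
#'   10 s segments, decompose each segment into independent components,
#'   flag artifactual components by kurtosis, skewness and a low-frequency
#'   spectral criterion, estimate each flagged component's artifact as its
#'   FDR-significant wavelet part and subtract it, then remix. Unflagged
#'   components pass through untouched, so a clean segment round-trips.
#' @name artifact-cleaning
NULL

#' Split a continuous recording into non-overlapping segments
#'
#' @param X sensors x samples matrix.
#' @param fs sampling rate in Hz.
#' @param seconds segment length (default 10 s). The trailing remainder
#'   (fewer than `fs * seconds` samples) is dropped; the dropped count is
#'   reported as attribute `dropped_samples`.
#' @return list of sensors x (fs*seconds) matrices.
#' @export
segment_continuous <- function(X, fs, seconds = 10) {
  if (!is.matrix(X)) stop_invalid("X must be a matrix (sensors x samples)")
  len <- as.integer(round(fs * seconds))
  if (ncol(X) < len)
    stop_invalid(sprintf("recording shorter than one segment (%d samples)", len))
  k <- ncol(X) %/% len
  segs <- lapply(seq_len(k), function(i) X[, ((i - 1) * len + 1):(i * len),
                                           drop = FALSE])
  attr(segs, "dropped_samples") <- ncol(X) - k * len
  segs
}

## symmetric FastICA (tanh contrast) on whitened data; deterministic under
## the given seed. No ICA package ships with the environment; the contract
## here is only determinism, non-Gaussianity maximisation and the exact
## round-trip mixing %*% sources + rowmeans == segment.
fastica_core <- function(Z, n_comp, seed, max_iter = 500L, tol = 1e-8) {
  W <- with_seed(seed, matrix(stats::rnorm(n_comp^2), n_comp))
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  Tn <- ncol(Z)
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    G <- tanh(U)
    Gp <- 1 - G^2
    W1 <- orth(G %*% t(Z) / Tn - diag(rowMeans(Gp)) %*% W)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Decompose a segment into independent components
#'
#' Whitens the (row-centred) segment by PCA and runs symmetric FastICA with
#' a tanh contrast under a fixed seed. `mixing %*% sources + center` equals
#' the input to numerical precision.
#'
#' @param segment sensors x samples matrix, full rank, with many more
#'   samples than sensors.
#' @param seed RNG seed for the unmixing initialisation (default 1).
#' @return list with `mixing` (S x S), `unmixing`, `sources` (S x T) and
#'   `center` (per-channel means).
#' @export
decompose_ica <- function(segment, seed = 1L) {
  if (!is.matrix(segment) || ncol(segment) <= nrow(segment))
    stop_invalid("segment must be sensors x samples with T > S")
  S <- nrow(segment)
  center <- rowMeans(segment)
  Xc <- segment - center
  covm <- tcrossprod(Xc) / (ncol(Xc) - 1)
  e <- eigen(symmetrize(covm), symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values))
    stop_invalid("rank-deficient segment: add a small ridge or drop a channel")
  K <- diag(1 / sqrt(e$values)) %*% t(e$vectors)   # whitening
  Kinv <- e$vectors %*% diag(sqrt(e$values))
  Z <- K %*% Xc
  W <- fastica_core(Z, S, seed)
  unmixing <- W %*% K
  mixing <- Kinv %*% t(W)
  list(mixing = mixing, unmixing = unmixing,
       sources = unmixing %*% Xc, center = center)
}

#' Flag artifactual independent components
#'
#' A component is flagged when its excess kurtosis exceeds `kurt_thr` in
#' magnitude (spiky muscular/blink activity), its skewness exceeds
#' `skew_thr` in magnitude (asymmetric ocular deflections), or the fraction
#' of its power below `lf_hz` exceeds `lf_fraction` (slow ocular drift
#' signature). The spectral rule replaces by-eye spectrum inspection with a
#' fixed, auditable criterion.
#'
#' @param sources components x samples matrix from [decompose_ica()].
#' @param fs sampling rate in Hz.
#' @param kurt_thr excess-kurtosis threshold (default 5).
#' @param skew_thr skewness threshold (default 2).
#' @param lf_hz low-frequency band edge in Hz (default 3).
#' @param lf_fraction flagging threshold on the low-frequency power fraction
#'   (default 0.6).
#' @return a data.frame of class `component_flags` with per-component
#'   `kurtosis`, `skewness`, `lf_power_fraction`, logical `flag`, and a
#'   `reasons` string.
#' @export
flag_components <- function(sources, fs, kurt_thr = 5, skew_thr = 2,
                            lf_hz = 3, lf_fraction = 0.6) {
  if (!is.matrix(sources)) stop_invalid("sources must be a matrix")
  stats_one <- function(x) {
    x <- x - mean(x)
    s2 <- mean(x^2)
    kur <- if (s2 > 0) mean(x^4) / s2^2 - 3 else 0
    ske <- if (s2 > 0) mean(x^3) / s2^1.5 else 0
    pw <- Mod(stats::fft(x))^2
    half <- pw[seq_len(floor(length(x) / 2)) + 1] # drop DC, keep one side
    freqs <- (seq_along(half)) * fs / length(x)
    lf <- if (sum(half) > 0) sum(half[freqs < lf_hz]) / sum(half) else 0
    c(kur, ske, lf)
  }
  st <- t(apply(sources, 1, stats_one))
  flags <- data.frame(
    component = seq_len(nrow(sources)),
    kurtosis = st[, 1], skewness = st[, 2], lf_power_fraction = st[, 3])
  crit <- cbind(kurtosis = abs(flags$kurtosis) > kurt_thr,
                skewness = abs(flags$skewness) > skew_thr,
                low_freq = flags$lf_power_fraction > lf_fraction)
  flags$flag <- rowSums(crit) > 0
  flags$reasons <- apply(crit, 1, function(r)
    paste(colnames(crit)[r], collapse = "+"))
  class(flags) <- c("component_flags", "data.frame")
  flags
}

#' Remix components into a multichannel signal
#'
#' Flagged components are replaced by their supplied corrected versions;
#' unflagged components pass through unchanged. With no flags the input
#' segment is reproduced exactly.
#'
#' @param mixing S x S mixing matrix from [decompose_ica()].
#' @param sources original components x samples matrix.
#' @param flags logical vector (or `component_flags`) marking components to
#'   replace.
#' @param corrected list (or matrix) of replacement rows for the flagged
#'   components, in component order.
#' @param center per-channel means to restore (default 0).
#' @return the reconstructed sensors x samples matrix.
#' @export
reconstruct <- function(mixing, sources, flags, corrected = NULL, center = 0) {
  if (inherits(flags, "component_flags")) flags <- flags$flag
  if (length(flags) != nrow(sources))
    stop_invalid("one flag per component required")
  out <- sources
  if (any(flags)) {
    if (is.null(corrected)) stop_invalid("corrected components missing")
    if (is.list(corrected)) corrected <- do.call(rbind, corrected)
    if (!all(dim(corrected) == c(sum(flags), ncol(sources))))
      stop_invalid("corrected components have the wrong shape")
    out[flags, ] <- corrected
  }
  mixing %*% out + center
}

#' Clean one segment by wavelet-ICA
#'
#' Runs [decompose_ica()], [flag_components()], corrects each flagged
#' component by subtracting its FDR-significant wavelet part (the artifact
#' estimate from [wavelet_shrink()]; the sub-threshold residual is the
#' retained background activity), and remixes.
#'
#' @param segment sensors x samples matrix.
#' @param fs sampling rate in Hz.
#' @param seed ICA seed.
#' @param fdr_q FDR level for the wavelet artifact estimate.
#' @param levels wavelet decomposition depth.
#' @param ... thresholds passed to [flag_components()].
#' @return list with `cleaned` (matrix) and `flags` (`component_flags`).
#' @export
clean_segment <- function(segment, fs, seed = 1L, fdr_q = 0.05, levels = 5L,
                          ...) {
  dec <- decompose_ica(segment, seed = seed)
  flags <- flag_components(dec$sources, fs, ...)
  corrected <- NULL
  if (any(flags$flag)) {
    corrected <- lapply(which(flags$flag), function(i) {
      s <- dec$sources[i, ]
      s - wavelet_shrink(s, fdr_q = fdr_q, levels = levels)
    })
  }
  list(cleaned = reconstruct(dec$mixing, dec$sources, flags$flag, corrected,
                             dec$center),
       flags = flags)
}

#' Clean a continuous recording segment by segment
#'
#' Applies [clean_segment()] to consecutive non-overlapping windows and
#' concatenates the results; the trailing remainder shorter than one segment
#' is passed through unchanged.
#'
#' @param X sensors x samples matrix.
#' @param fs sampling rate in Hz.
#' @param seconds segment length in seconds (default 10).
#' @param seed ICA seed (incremented per segment).
#' @param ... passed to [clean_segment()].
#' @return list with `cleaned` (matrix, same shape as `X`) and `flags`
#'   (list of per-segment `component_flags`).
#' @export
clean_continuous <- function(X, fs, seconds = 10, seed = 1L, ...) {
  segs <- segment_continuous(X, fs, seconds)
  res <- lapply(seq_along(segs), function(i)
    clean_segment(segs[[i]], fs, seed = seed + i - 1L, ...))
  cleaned <- do.call(cbind, lapply(res, `[[`, "cleaned"))
  used <- ncol(cleaned)
  if (used < ncol(X)) cleaned <- cbind(cleaned, X[, (used + 1):ncol(X),
                                                 drop = FALSE])
  list(cleaned = cleaned, flags = lapply(res, `[[`, "flags"))
}
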