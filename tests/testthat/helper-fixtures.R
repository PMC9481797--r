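# shared fixtures, all generated in code under fixed seeds

rand_spd_fixture <- function(S, seed = NULL) {
  draw <- function() {
    A <- matrix(rnorm(S * (S + 4)), S)
    tcrossprod(A) / (S + 4)
  }
  if (is.null(seed)) draw() else riemeeg:::with_seed(seed, draw())
}

rand_spd_list <- function(n, S, seed) {
  riemeeg:::with_seed(seed, lapply(seq_len(n), function(i) rand_spd_fixture(S)))
}

# small fast synthetic trial set for decoder unit tests: fewer samples, three
# bands' worth of content but full standard band structure
tiny_config <- function(seed = 7) {
  synth_config(S = 4L, fs = 200, trial_seconds = c(1.2, 1.6), n_subjects = 2L,
               n_groups = 4L, views_per_group = 2L,
               informative_bands = "beta2", effect_size = 2.5,
               subject_shift_scale = 0.3, seed = seed)
}

# three-band decoder configuration for fast unit tests (odd count, majority 2)
fast_config <- function(...) {
  bands <- standard_bands()[c(2, 6, 7), ]
  decoder_config(bands = bands, ...)
}

# brute-force minimum spanning tree: enumerate all (N-1)-edge subsets
brute_mst_weight <- function(points) {
  D <- as.matrix(dist(points))
  n <- nrow(D)
  pairs <- t(combn(n, 2))
  best <- Inf
  for (sel in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    e <- pairs[sel, , drop = FALSE]
    # connectivity check by union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (r in seq_len(nrow(e))) {
      a <- find(e[r, 1]); b <- find(e[r, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(D[e]))
  }
  best
}

# synthetic blink benchmark: band-limited clean EEG plus a large, smooth,
# frontally weighted pulse train mimicking ocular artifacts
make_blink_recording <- function(seed, fs = 200, seconds = 10, S = 4) {
  riemeeg:::with_seed(seed, {
    n <- fs * seconds
    mix <- matrix(rnorm(S * S, sd = 0.4), S) + diag(S)
    src <- matrix(rnorm(S * n), S)
    for (ch in seq_len(S)) src[ch, ] <- bandpass(matrix(src[ch, ], 1),
                                                 c(2, 40), fs)[1, ]
    clean <- mix %*% src
    blink <- numeric(n)
    for (t0 in sort(sample(seq(fs, n - fs), 6)))
      blink[t0:(t0 + fs / 4)] <- blink[t0:(t0 + fs / 4)] +
        20 * sin(seq(0, pi, length.out = fs / 4 + 1))^2
    pattern <- c(1, 0.8, rep(0.1, S - 2))
    list(clean = clean, dirty = clean + outer(pattern, blink))
  })
}
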