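#' @title Multivariate Wald-Wolfowitz separability score
#' @description The Friedman-Rafsky generalisation of the Wald-Wolfowitz
#'   runs test to multivariate samples: build the Euclidean minimal spanning
#'   tree (MST) of the pooled points, delete every edge joining points of
#'   opposite class, and count the resulting subtrees R (the "runs"). Few
#'   runs mean the classes occupy separate regions; the standardized
#'   statistic (the ww-score) is R centred and scaled by its exact
#'   permutation-null mean and variance conditional on the tree, so low
#'   (strongly negative) scores indicate high class separability.
#' @name wwtest
NULL

#' Minimal spanning tree of a point cloud
#'
#' Prim's algorithm on Euclidean distances with deterministic lexicographic
#' tie-breaking (lowest node index wins), so degenerate configurations give
#' a reproducible tree.
#'
#' @param points N x d coordinate matrix (N >= 2).
#' @return an (N-1) x 2 integer matrix of edges; columns `i`, `j` with
#'   `i < j` per row.
#' @export
minimum_spanning_tree <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop_invalid("need at least 2 points")
  D <- as.matrix(stats::dist(points))
  if (all(D[upper.tri(D)] == 0))
    warning("all points identical: MST is tie-broken by node order")
  mind <- D[1, ]
  parent <- rep(1L, n)
  intree <- rep(FALSE, n); intree[1] <- TRUE
  mind[1] <- Inf
  edges <- matrix(0L, n - 1, 2)
  for (s in seq_len(n - 1)) {
    j <- which.min(replace(mind, intree, Inf)) # first index wins ties
    edges[s, ] <- sort(c(parent[j], j))
    intree[j] <- TRUE
    upd <- !intree & D[j, ] < mind
    mind[upd] <- D[j, upd]
    parent[upd] <- j
  }
  colnames(edges) <- c("i", "j")
  edges
}

#' Multivariate Wald-Wolfowitz (MST runs) two-sample test
#'
#' Computes the runs count R over the pooled MST, the Friedman-Rafsky null
#' mean and variance conditional on the tree, the standardized ww-score
#' \eqn{(R - E[R]) / \sqrt{Var[R]}} (an asymptotic z-statistic), its normal
#' lower-tail p-value, and a seeded permutation p-value. The test is
#' one-sided toward few runs: separated classes produce R far below its null
#' expectation.
#'
#' @param points N x d embedded coordinates.
#' @param labels binary (two-level) class labels, one per point; both classes
#'   need at least 2 points.
#' @param n_permutations label permutations for the permutation p-value
#'   (default 10000); fewer than 100 triggers a warning.
#' @param seed RNG seed for the permutations.
#' @return an object of class `ww_result` with fields `runs_count`,
#'   `expected_runs`, `variance_runs`, `ww_score`, `asymptotic_p`,
#'   `permutation_p`, `n_edges`, `sample_sizes`.
#' @export
ww_test <- function(points, labels, n_permutations = 10000L, seed = 1L) {
  points <- as.matrix(points)
  if (nrow(points) != length(labels))
    stop_invalid("one label per point required")
  lab <- as.integer(factor(labels))
  tab <- tabulate(lab, 2)
  if (any(tab == 0)) stop_invalid("both classes must be nonempty")
  if (any(tab == 1)) stop_invalid("a one-point class is not testable")
  if (n_permutations < 100)
    warning("fewer than 100 permutations gives a coarse p-value")
  edges <- minimum_spanning_tree(points)
  n1 <- tab[1]; n2 <- tab[2]; N <- n1 + n2
  deg <- tabulate(as.vector(edges), N)
  C <- sum(deg * (deg - 1) / 2)
  runs <- function(l) sum(l[edges[, 1]] != l[edges[, 2]]) + 1L
  R <- runs(lab)
  ER <- 2 * n1 * n2 / N + 1
  VR <- (2 * n1 * n2 / (N * (N - 1))) *
    ((2 * n1 * n2 - N) / N +
       ((C - N + 2) / ((N - 2) * (N - 3))) * (N * (N - 1) - 4 * n1 * n2 + 2))
  z <- (R - ER) / sqrt(VR)
  Rperm <- with_seed(seed, vapply(seq_len(n_permutations),
                                  function(b) runs(sample(lab)), integer(1)))
  structure(list(
    runs_count = R,
    expected_runs = ER,
    variance_runs = VR,
    ww_score = z,
    asymptotic_p = stats::pnorm(z),
    permutation_p = (1 + sum(Rperm <= R)) / (n_permutations + 1),
    n_edges = nrow(edges),
    sample_sizes = c(n1, n2)
  ), class = "ww_result")
}

#' @export
print.ww_result <- function(x, ...) {
  cat(sprintf(
    "<ww_result> R = %d (expected %.2f), ww-score = %.3f, permutation p = %.4g, asymptotic p = %.4g (m = %d, n = %d)\n",
    x$runs_count, x$expected_runs, x$ww_score, x$permutation_p,
    x$asymptotic_p, x$sample_sizes[1], x$sample_sizes[2]))
  invisible(x)
}
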