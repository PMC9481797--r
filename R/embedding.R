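#' @title Distance-preserving embedding with out-of-sample extension
#' @description Classical (Torgerson) multidimensional scaling of the
#'   inter-trial AIRM distance matrix, producing the Euclidean feature
#'   vectors fed to the per-band classifiers, plus the Nystroem out-of-sample
#'   extension that places an unseen (aligned) SCM into the learned space
#'   from its distances to the training SCMs. The spectral form is required:
#'   the out-of-sample projection reuses the training eigenpairs and
#'   centering terms.
#' @name embedding
NULL

#' Fit a classical MDS embedding from a distance matrix
#'
#' Double-centers \eqn{-\tfrac12 D^2}, eigendecomposes, and keeps the top
#' `d` coordinates scaled by the square roots of the eigenvalues. AIRM
#' distance matrices are not exactly Euclidean, so some eigenvalues are
#' negative; these are dropped (never sign-flipped) and their share of total
#' spectral mass is stored as the distortion diagnostic `neg_mass`.
#'
#' @param D symmetric, zero-diagonal distance matrix (N >= 3).
#' @param d embedding dimension, or `"auto"` (default) to keep every
#'   eigenvalue above `1e-9` times the largest.
#' @return an object of class `mds_embedding` with elements `coords` (N x d),
#'   `eigenvalues`, `eigenvectors`, `row_means`/`grand_mean` (centering terms
#'   of the squared distances), `ids`, `d`, `neg_mass`.
#' @export
fit_mds <- function(D, d = "auto") {
  if (!is.matrix(D) || nrow(D) != ncol(D) || !all(is.finite(D)))
    stop_invalid("D must be a finite square matrix")
  n <- nrow(D)
  if (n < 3) stop_invalid("need at least 3 points")
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D))) || any(abs(diag(D)) > 1e-12))
    stop_invalid("D must be symmetric with a zero diagonal")
  ids <- rownames(D) %||% as.character(seq_len(n))
  D2 <- D^2
  row_means <- rowMeans(D2)
  grand_mean <- mean(D2)
  B <- -0.5 * (D2 - outer(row_means, rep(1, n)) -
                 outer(rep(1, n), row_means) + grand_mean)
  e <- eigen(symmetrize(B), symmetric = TRUE)
  pos <- which(e$values > 1e-9 * max(e$values, 0))
  if (identical(d, "auto")) {
    keep <- pos
  } else {
    d <- as.integer(d)
    if (length(pos) < d)
      stop_invalid(sprintf(
        "only %d positive eigenvalues available; requested d = %d",
        length(pos), d))
    keep <- pos[seq_len(d)]
  }
  vec <- e$vectors[, keep, drop = FALSE]
  # canonical sign: largest-magnitude loading positive, for reproducibility
  for (k in seq_len(ncol(vec))) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  val <- e$values[keep]
  total_mass <- sum(abs(e$values))
  structure(list(
    coords = vec %*% diag(sqrt(val), length(val)),
    eigenvalues = val,
    eigenvectors = vec,
    row_means = row_means,
    grand_mean = grand_mean,
    ids = ids,
    d = length(val),
    neg_mass = if (total_mass > 0) sum(abs(e$values[e$values < 0])) / total_mass else 0
  ), class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf(
    "<mds_embedding> %d training points, d = %d, negative spectral mass = %.2e\n",
    length(x$ids), x$d, x$neg_mass))
  invisible(x)
}

#' Training coordinates of a fitted embedding
#'
#' @param model an `mds_embedding`.
#' @return the N x d coordinate matrix, rows in training order.
#' @export
embed_training <- function(model) {
  stopifnot(inherits(model, "mds_embedding"))
  out <- model$coords
  rownames(out) <- model$ids
  out
}

#' Out-of-sample extension: embed a new point from its training distances
#'
#' Nystroem projection of an unseen point: with squared distances
#' \eqn{d^2(x, x_i)} to the training points, the kernel value to training
#' point i is \eqn{-\tfrac12 (d^2(x, x_i) - r_i - \bar{d}^2(x) + g)} where
#' \eqn{r_i} and g are the training row means and grand mean, and coordinate
#' k is \eqn{\sum_i v_{ik} \kappa_i / \sqrt{\lambda_k}}. For a training
#' point's own distance row this reproduces its training coordinates.
#'
#' @param model an `mds_embedding`.
#' @param dist_to_training numeric vector of distances from the new point to
#'   every training point, in training order.
#' @return length-d coordinate vector.
#' @export
embed_oos <- function(model, dist_to_training) {
  stopifnot(inherits(model, "mds_embedding"))
  n <- length(model$ids)
  if (length(dist_to_training) != n)
    stop_invalid(sprintf("expected %d distances, got %d",
                         n, length(dist_to_training)))
  d2 <- dist_to_training^2
  kern <- -0.5 * (d2 - model$row_means - mean(d2) + model$grand_mean)
  as.numeric(crossprod(model$eigenvectors, kern) / sqrt(model$eigenvalues))
}
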