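#' @title SPD matrix algebra for EEG covariance descriptors
#' @description Sample covariance estimation, the affine-invariant Riemannian
#'   metric (AIRM), geodesics and the Karcher/Frechet mean on the manifold of
#'   symmetric positive-definite (SPD) matrices. A band-passed EEG trial
#'   \eqn{X \in R^{S \times T}} (sensors x samples) is summarised by its
#'   spatial covariance \eqn{C = XX'/(T-1)}, an SPD point; all downstream
#'   learning operates on the geometry these functions define.
#' @name spd-geometry
NULL

symmetrize <- function(M) (M + t(M)) / 2

#' Test whether a matrix is symmetric positive-definite
#'
#' Symmetry is checked relative to the Frobenius norm (tolerance `tol`);
#' positive-definiteness requires all eigenvalues strictly positive.
#'
#' @param C numeric matrix.
#' @param tol relative symmetry tolerance.
#' @return logical scalar.
#' @export
is_spd <- function(C, tol = 1e-10) {
  if (!is.matrix(C) || nrow(C) != ncol(C) || !all(is.finite(C))) return(FALSE)
  nf <- norm(C, "F")
  if (nf == 0) return(FALSE)
  if (norm(C - t(C), "F") > tol * max(nf, 1)) return(FALSE)
  ev <- eigen(symmetrize(C), symmetric = TRUE, only.values = TRUE)$values
  all(ev > 0)
}

assert_spd <- function(C, what = "matrix") {
  if (!is_spd(C)) stop_invalid(what, " is not symmetric positive-definite")
  invisible(C)
}

## Matrix functions by symmetric eigendecomposition. Eigenvalues are clipped
## at `floor` before log/negative powers: short 8-channel trials can be
## numerically near-singular even after ridge regularization.
spd_map <- function(C, f, floor = .Machine$double.eps) {
  e <- eigen(symmetrize(C), symmetric = TRUE)
  v <- pmax(e$values, floor)
  symmetrize(e$vectors %*% (f(v) * t(e$vectors)))
}

spd_sqrt    <- function(C) spd_map(C, sqrt)
spd_invsqrt <- function(C) spd_map(C, function(v) 1 / sqrt(v))
spd_logm    <- function(C) spd_map(C, log)

## Matrix exponential of a symmetric matrix (eigenvalues unrestricted).
sym_expm <- function(S) {
  e <- eigen(symmetrize(S), symmetric = TRUE)
  symmetrize(e$vectors %*% (exp(e$values) * t(e$vectors)))
}

#' Estimate the sample covariance matrix (SCM) of a trial
#'
#' Computes \eqn{C = XX'/(T-1)} for a sensors-by-samples trial matrix. If the
#' smallest eigenvalue falls below `ridge_factor` times the mean diagonal
#' element, a ridge is added to restore strict positive-definiteness and a
#' warning is emitted. Signals are used as given (no mean removal): band-pass
#' filtered EEG is zero-mean by construction.
#'
#' @param X numeric matrix, sensors in rows, temporal samples in columns.
#' @param ridge_factor relative eigenvalue floor (default `1e-10`).
#' @return an SPD matrix of size sensors x sensors.
#' @examples
#' estimate_scm(matrix(c(1, 2, -1, 0), 2, 2))
#' @export
estimate_scm <- function(X, ridge_factor = 1e-10) {
  if (!is.matrix(X) || !all(is.finite(X)))
    stop_invalid("trial matrix must be numeric and finite")
  Tn <- ncol(X)
  if (Tn < 2) stop_invalid("trial must have at least 2 temporal samples")
  C <- tcrossprod(X) / (Tn - 1)
  C <- symmetrize(C)
  floor_ev <- ridge_factor * mean(diag(C))
  if (floor_ev <= 0) floor_ev <- ridge_factor
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < floor_ev) {
    eps <- floor_ev - min(ev_min, 0)
    C <- C + diag(eps, nrow(C))
    warning(sprintf(
      "near-singular SCM (min eigenvalue %.3e): ridge %.3e added", ev_min, eps))
  }
  C
}

#' AIRM geodesic distance between two SPD matrices
#'
#' \deqn{\delta(C_1, C_2) = \| \mathrm{logm}(C_1^{-1/2} C_2 C_1^{-1/2}) \|_F
#'   = \sqrt{\sum_k \log^2 \lambda_k(C_1^{-1} C_2)},}
#' the geodesic distance induced by the affine-invariant Riemannian metric.
#' It is invariant under any joint congruence \eqn{C \mapsto W C W'} and under
#' joint positive rescaling, which is what makes covariance descriptors with
#' arbitrary amplifier gain comparable.
#'
#' @param C1,C2 SPD matrices of equal size.
#' @return nonnegative scalar distance.
#' @export
airm_distance <- function(C1, C2) {
  assert_spd(C1, "C1"); assert_spd(C2, "C2")
  if (!all(dim(C1) == dim(C2))) stop_invalid("C1 and C2 differ in size")
  W <- spd_invsqrt(C1)
  M <- symmetrize(W %*% C2 %*% W)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(pmax(ev, .Machine$double.eps))^2))
}

#' Point along the AIRM geodesic between two SPD matrices
#'
#' Returns \eqn{C_1^{1/2} (C_1^{-1/2} C_2 C_1^{-1/2})^t C_1^{1/2}} for
#' \eqn{t \in [0, 1]}; `t = 0` gives `C1`, `t = 1` gives `C2`.
#'
#' @param C1,C2 SPD endpoints.
#' @param t interpolation parameter in `[0, 1]`.
#' @return an SPD matrix.
#' @export
geodesic_point <- function(C1, C2, t) {
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1)
    stop_invalid("t must be a scalar in [0, 1]")
  if (t == 0) return(C1)
  if (t == 1) return(C2)
  assert_spd(C1, "C1"); assert_spd(C2, "C2")
  S  <- spd_sqrt(C1)
  Wi <- spd_invsqrt(C1)
  M  <- spd_map(symmetrize(Wi %*% C2 %*% Wi), function(v) v^t)
  symmetrize(S %*% M %*% S)
}

#' Karcher (Frechet) mean of a set of SPD matrices
#'
#' Finds the point \eqn{\bar{B}} minimising the sum of squared AIRM distances
#' to the set, by fixed-point iteration in the tangent space: at the current
#' iterate \eqn{B}, the update direction is the tangent-space average
#' \eqn{S = N^{-1} \sum_i \mathrm{logm}(B^{-1/2} C_i B^{-1/2})} and the new
#' iterate is \eqn{B^{1/2} \mathrm{expm}(S) B^{1/2}} (unit step, halved
#' deterministically whenever it fails to decrease the objective — the
#' plain unit step can overshoot on widely dispersed sets). Initialisation
#' is the log-Euclidean mean. Convergence is declared when
#' \eqn{\|S\|_F <} `tol`, or earlier at numerical stationarity: when no
#' representable step along the descent direction decreases the objective,
#' the iterate is returned as the mean at attainable floating-point
#' precision (for very dispersed, ill-conditioned sets the gradient-norm
#' floor can sit above an absolute `tol`).
#'
#' @param mats list of SPD matrices of a common size.
#' @param tol Frobenius norm of the tangent-space update at convergence.
#' @param max_iter iteration cap; non-convergence raises a condition of class
#'   `karcher_no_convergence` carrying the last iterate (`iterate`) and the
#'   residual update norm (`residual`).
#' @return the Frechet mean, an SPD matrix.
#' @export
karcher_mean <- function(mats, tol = 1e-9, max_iter = 200L) {
  if (!is.list(mats) || length(mats) == 0)
    stop_invalid("need a nonempty list of SPD matrices")
  for (i in seq_along(mats)) assert_spd(mats[[i]], sprintf("matrix %d", i))
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(M) all(dim(M) == d), logical(1))))
    stop_invalid("matrices differ in size")
  if (length(mats) == 1) return(mats[[1]])
  # tangent-space mean (negative gradient direction) and the objective
  # value sum_i delta^2(C_i, B) from one whitening pass
  tangent_state <- function(B) {
    W <- spd_invsqrt(B)
    logs <- lapply(mats, function(C) spd_logm(symmetrize(W %*% C %*% W)))
    list(S = Reduce(`+`, logs) / length(logs),
         f = sum(vapply(logs, function(L) sum(L^2), numeric(1))))
  }
  # log-Euclidean initialisation: for dispersed sets it starts far closer to
  # the optimum than the arithmetic mean (and is exact for commuting sets)
  B <- sym_expm(Reduce(`+`, lapply(mats, spd_logm)) / length(mats))
  st <- tangent_state(B)
  res <- norm(st$S, "F")
  for (it in seq_len(max_iter)) {
    if (res < tol) return(B)
    # unit step through the exponential map, halved (deterministically) until
    # the Armijo sufficient-decrease condition holds: the plain unit step
    # can overshoot and zigzag on widely dispersed sets. The directional
    # derivative of the objective along S is -2N |S|_F^2.
    Sq <- spd_sqrt(B)
    step <- 1
    decrease <- 0.5 * length(mats) * res^2 # c1 = 0.25 of the derivative
    repeat {
      B_new <- symmetrize(Sq %*% sym_expm(step * st$S) %*% Sq)
      st_new <- tangent_state(B_new)
      # accept on sufficient objective decrease, or on strong gradient
      # contraction (near the optimum the objective decrement drops below
      # floating-point noise while the fixed-point map still contracts)
      if (st_new$f <= st$f - step * decrease ||
          norm(st_new$S, "F") <= 0.5 * res) break
      if (step <= 2^-12) {
        # numerical stationarity: no representable step along the descent
        # direction lowers the objective any further, so the current
        # iterate is the mean to attainable floating-point precision
        return(B)
      }
      step <- step / 2
    }
    B <- B_new; st <- st_new; res <- norm(st$S, "F")
  }
  stop(errorCondition(
    sprintf("Karcher mean did not converge in %d iterations (residual %.3e)",
            max_iter, res),
    class = c("karcher_no_convergence", "error"),
    iterate = B, residual = res))
}

#' Pairwise AIRM distance matrix of a set of SPD matrices
#'
#' @param mats list of SPD matrices of a common size.
#' @param ids optional identifiers used as dimnames (defaults to positions).
#' @return a symmetric, zero-diagonal numeric matrix of AIRM distances.
#' @export
pairwise_airm <- function(mats, ids = NULL) {
  n <- length(mats)
  if (n == 0) stop_invalid("need a nonempty list of SPD matrices")
  ids <- ids %||% as.character(seq_len(n))
  # precompute the whitening factor of each matrix once
  wh <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is_spd(mats[[i]]))
      stop_invalid(sprintf("matrix %s is not SPD", ids[i]))
    wh[[i]] <- spd_invsqrt(mats[[i]])
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      M <- symmetrize(wh[[i]] %*% mats[[j]] %*% wh[[i]])
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      D[i, j] <- D[j, i] <- sqrt(sum(log(pmax(ev, .Machine$double.eps))^2))
    }
  }
  D
}
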