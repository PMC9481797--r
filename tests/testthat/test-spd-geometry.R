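test_that("estimate_scm matches direct arithmetic and a brute-force oracle", {
  # hand-computable 2x2 case, T - 1 = 1
  X <- matrix(c(1, 2, -1, 0), 2, 2)
  expect_equal(estimate_scm(X), matrix(c(2, 2, 2, 4), 2, 2))

  # elementwise sum-of-products oracle on a long random trial
  set.seed(11)
  X <- matrix(rnorm(4 * 1000), 4, 1000)
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) oracle[i, j] <- sum(X[i, ] * X[j, ]) / 999
  expect_lt(max(abs(estimate_scm(X) - oracle)), 1e-12)
})

test_that("estimate_scm regularizes degenerate input and rejects bad input", {
  expect_warning(C <- estimate_scm(matrix(0, 3, 10)), "ridge")
  expect_true(is_spd(C))
  expect_error(estimate_scm(matrix(1, 2, 1)), "2 temporal samples")
  expect_error(estimate_scm(matrix(c(1, NA, 0, 1), 2, 2)), "finite")
})

test_that("airm_distance agrees with the eigenvalue closed form", {
  expect_equal(airm_distance(diag(3), diag(3)), 0)
  expect_equal(airm_distance(diag(c(exp(1)^2, 1)), diag(2)), 2)

  set.seed(21)
  for (r in 1:5) {
    C1 <- rand_spd_fixture(5)
    C2 <- rand_spd_fixture(5)
    lam <- eigen(solve(C1) %*% C2, only.values = TRUE)$values
    oracle <- sqrt(sum(log(Re(lam))^2))
    expect_lt(abs(airm_distance(C1, C2) - oracle), 1e-9)
    expect_equal(airm_distance(C1, C2), airm_distance(C2, C1), tolerance = 1e-10)
  }
  expect_error(airm_distance(diag(2), diag(3)), "size")
  expect_error(airm_distance(diag(c(1, -1)), diag(2)), "positive-definite")
})

test_that("AIRM satisfies affine/scale invariance and the metric axioms", {
  set.seed(31)
  for (r in 1:10) {
    C1 <- rand_spd_fixture(4); C2 <- rand_spd_fixture(4); C3 <- rand_spd_fixture(4)
    W <- matrix(rnorm(16), 4)
    tr <- function(C) riemeeg:::symmetrize(W %*% C %*% t(W))
    d0 <- airm_distance(C1, C2)
    expect_lt(abs(airm_distance(tr(C1), tr(C2)) - d0), 1e-8)
    expect_lt(abs(airm_distance(3.7 * C1, 3.7 * C2) - d0), 1e-8)
    # triangle inequality
    expect_lte(d0, airm_distance(C1, C3) + airm_distance(C3, C2) + 1e-10)
  }
})

test_that("geodesic interpolation hits its endpoints and the commuting midpoint", {
  C1 <- rand_spd_fixture(3, seed = 41)
  C2 <- rand_spd_fixture(3, seed = 42)
  expect_identical(geodesic_point(C1, C2, 0), C1)
  expect_identical(geodesic_point(C1, C2, 1), C2)
  expect_equal(geodesic_point(diag(2), diag(c(4, 9)), 0.5), diag(c(2, 3)),
               tolerance = 1e-12)
  expect_error(geodesic_point(C1, C2, 1.2), "\\[0, 1\\]")
})

test_that("karcher_mean solves commuting sets in closed form", {
  C <- rand_spd_fixture(4, seed = 51)
  expect_identical(karcher_mean(list(C)), C)
  # commuting diagonal set: mean is exp of the mean log, entrywise
  ds <- list(diag(c(1, 1)), diag(c(4, 9)))
  expect_equal(karcher_mean(ds), diag(c(2, 3)), tolerance = 1e-8)
  ds3 <- list(diag(c(1, 8)), diag(c(2, 1)), diag(c(4, 27)))
  expect_equal(karcher_mean(ds3), diag(c(2, 6)), tolerance = 1e-8)
})

test_that("karcher_mean is congruence-equivariant, order-invariant, and certified", {
  set.seed(61)
  mats <- rand_spd_list(10, 4, seed = 62)
  A <- matrix(rnorm(16), 4)
  m1 <- karcher_mean(mats)
  m2 <- karcher_mean(lapply(mats, function(C) riemeeg:::symmetrize(A %*% C %*% t(A))))
  expect_lt(norm(m2 - riemeeg:::symmetrize(A %*% m1 %*% t(A)), "F"), 1e-7)

  m3 <- karcher_mean(rev(mats))
  expect_lt(airm_distance(m1, m3), 1e-7)

  # gradient-norm certificate at the solution
  W <- riemeeg:::spd_invsqrt(m1)
  grad <- Reduce(`+`, lapply(mats, function(C)
    riemeeg:::spd_logm(riemeeg:::symmetrize(W %*% C %*% W))))
  expect_lt(norm(grad, "F"), 1e-9 * length(mats))
})

test_that("karcher_mean signals non-convergence with its last iterate", {
  mats <- rand_spd_list(5, 3, seed = 71)
  err <- tryCatch(karcher_mean(mats, tol = 1e-15, max_iter = 1L),
                  karcher_no_convergence = identity)
  expect_s3_class(err, "karcher_no_convergence")
  expect_true(is.matrix(err$iterate))
  expect_gt(err$residual, 0)
})

test_that("pairwise_airm builds a valid distance matrix and is affine-invariant", {
  C <- rand_spd_fixture(3, seed = 81)
  D0 <- pairwise_airm(list(C, C, C))
  expect_lt(max(D0), 1e-7)

  ds <- list(diag(c(1, 1)), diag(c(4, 1)), diag(c(1, 9)))
  D <- pairwise_airm(ds)
  expect_equal(D[1, 2], log(4))
  expect_equal(D[1, 3], log(9))
  expect_equal(D[2, 3], sqrt(log(4)^2 + log(9)^2))
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))

  mats <- rand_spd_list(5, 3, seed = 82)
  A <- riemeeg:::with_seed(83, matrix(rnorm(9), 3))
  Dt <- pairwise_airm(lapply(mats, function(C)
    riemeeg:::symmetrize(A %*% C %*% t(A))))
  expect_lt(max(abs(Dt - pairwise_airm(mats))), 1e-8)
})
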