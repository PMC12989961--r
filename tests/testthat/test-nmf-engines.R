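test_that("sedObjective and relativeFittingError match hand computations", {
  W <- matrix(c(1, 0), 2, 1); H <- matrix(c(1, 0), 1, 2)
  X1 <- matrix(c(2, 0, 0, 0), 2, 2)
  expect_equal(sedObjective(2 * X1 / 2, list(W = 2 * W, H = H)), 0)
  expect_equal(sedObjective(X1, list(W = W, H = 2 * H %*% diag(c(1, 0)))),
               0)
  X2 <- diag(c(2, 1))
  expect_equal(sedObjective(X2, list(W = 2 * W, H = H)), 0.5)
  expect_equal(relativeFittingError(X2, list(W = 2 * W, H = H)), 20)
  expect_equal(relativeFittingError(X1, list(W = 0 * W, H = H)), 100)
  expect_error(relativeFittingError(matrix(0, 2, 2), list(W = W, H = H)),
               "all-zero")
  expect_error(sedObjective(X1, list(W = matrix(1, 3, 1), H = H)),
               "incompatible")
})

test_that("the per-component convergence criterion behaves as specified", {
  W <- matrix(runif(8), 4, 2); H <- matrix(runif(6), 2, 3)
  a <- list(W = W, H = H)
  expect_true(nmfConverged(a, a, 1e-12))
  # doubling a column gives squared relative change 1/9
  b <- list(W = W %*% diag(c(2, 1)), H = H)
  expect_false(nmfConverged(a, b, 1e-4))
  expect_true(nmfConverged(a, b, 1 / 9 + 1e-12))
  # H change alone breaks convergence (conjunction over both factors)
  d <- list(W = W, H = H * matrix(c(3, 1), 2, 3))
  expect_false(nmfConverged(a, d, 1e-4))
  # dead component in both iterates counts as converged
  z <- list(W = cbind(W[, 1], 0), H = rbind(H[1, ], 0))
  expect_true(nmfConverged(z, z, 1e-8))
  expect_error(nmfConverged(a, list(W = W[, 1, drop = FALSE],
                                    H = H[1, , drop = FALSE]), 1e-4),
               "rank")
})

test_that("nndsvd initialization is nonnegative, deterministic and useful", {
  set.seed(41)
  X <- matrix(runif(80), 10, 8)
  f <- nndsvdInit(X, 3)
  expect_true(all(basisMatrix(f) >= 0) && all(coefMatrix(f) >= 0))
  expect_identical(basisMatrix(nndsvdInit(X, 3)), basisMatrix(f))
  expect_lt(sum((X - fitted(f))^2), sum(X^2))
  # rank-1: leading singular pair, no truncation needed (Perron-Frobenius)
  f1 <- nndsvdInit(X, 1)
  s <- truncatedSVD(X, 1)
  expect_equal(as.vector(basisMatrix(f1)), sqrt(s@sigma[1]) * s@U[, 1],
               tolerance = 1e-10)
  # variant "a" fills zeros; "ar" is seeded and reproducible
  expect_true(all(basisMatrix(nndsvdInit(X, 3, "a")) > 0))
  far <- nndsvdInit(X, 3, "ar", seed = 7)
  expect_true(all(basisMatrix(far) > 0))
  expect_identical(basisMatrix(nndsvdInit(X, 3, "ar", seed = 7)),
                   basisMatrix(far))
  expect_error(nndsvdInit(X, 11), "r")
})

test_that("nndsvd reproduces the reference truncation procedure", {
  set.seed(42)
  X <- matrix(runif(70), 10, 7)
  f <- nndsvdInit(X, 3)
  sv <- svd(X)
  for (j in 2:3) {
    u <- sv$u[, j]; v <- sv$v[, j]
    # fix the sign convention used by truncatedSVD
    i <- which.max(abs(u)); if (u[i] < 0) { u <- -u; v <- -v }
    mp <- sqrt(sum(pmax(u, 0)^2)) * sqrt(sum(pmax(v, 0)^2))
    mn <- sqrt(sum(pmax(-u, 0)^2)) * sqrt(sum(pmax(-v, 0)^2))
    sec <- if (mp >= mn) pmax(u, 0) / sqrt(sum(pmax(u, 0)^2)) else
      pmax(-u, 0) / sqrt(sum(pmax(-u, 0)^2))
    expect_equal(basisMatrix(f)[, j],
                 sqrt(sv$d[j] * max(mp, mn)) * sec, tolerance = 1e-10)
  }
})

test_that("HALS descends monotonically and fixes exact factorizations", {
  set.seed(43)
  for (i in 1:50) {
    m <- sample(5:40, 1); n <- sample(5:40, 1); r <- sample(2:6, 1)
    X <- randomPlanted(m, n, r)
    f <- runHALS(X, randomInit(X, r, seed = i),
                 convergenceControl(maxIter = 60, traceObjective = TRUE))
    expect_true(all(diff(objectiveTrace(f)$objective) <= 1e-10))
  }
  # strictly positive fixed point: immediate convergence, objective kept
  W <- matrix(runif(12, 0.5, 1), 4, 3); H <- matrix(runif(9, 0.5, 1), 3, 3)
  X <- W %*% H
  f <- runHALS(X, list(W = W, H = H), convergenceControl())
  expect_true(f@converged)
  expect_equal(f@iterations, 1L)
  expect_equal(basisMatrix(f), W, tolerance = 1e-12)
})

test_that("HALS error is monotone in rank from NNDSVD initialization", {
  set.seed(44)
  for (i in 1:20) {
    X <- randomPlanted(15, 12, 4, seed = 100 + i)
    errs <- sapply(1:4, function(r)
      relativeFittingError(X, runHALS(X, nndsvdInit(X, r),
                                      convergenceControl(maxIter = 400))))
    expect_true(all(diff(errs) <= 1e-8))
  }
})

test_that("rank-1 HALS attains the best rank-1 approximation", {
  set.seed(45)
  X <- matrix(runif(150), 15, 10)
  f <- runHALS(X, nndsvdInit(X, 1),
               convergenceControl(eps = 1e-10, maxIter = 3000))
  s <- truncatedSVD(X, 1)
  best <- sum((X - s@sigma[1] * s@U %*% t(s@V))^2)
  expect_lt(abs(sum((X - fitted(f))^2) - best), 1e-6 * best)
})

test_that("MU descends, locks zeros, and shares descent with HALS", {
  set.seed(46)
  X <- randomPlanted(12, 10, 3)
  init <- list(W = matrix(runif(36, 0.1, 1), 12, 3),
               H = matrix(runif(30, 0.1, 1), 3, 10))
  fmu <- runMU(X, init, convergenceControl(maxIter = 150,
                                           traceObjective = TRUE))
  expect_true(all(diff(objectiveTrace(fmu)$objective) <= 1e-12 +
                    1e-12 * objectiveTrace(fmu)$objective[-1]))
  # an exactly-zero component stays dead without a perturbation
  z <- init; z$W[, 2] <- 0; z$H[2, ] <- 0
  fz <- runMU(X, z, convergenceControl(maxIter = 30))
  expect_true(all(basisMatrix(fz)[, 2] == 0))
  expect_true(all(coefMatrix(fz)[2, ] == 0))
  # both engines reduce the objective from a shared positive start
  for (i in 1:50) {
    Xi <- randomPlanted(8, 7, 2, seed = 300 + i)
    ini <- list(W = matrix(runif(16, 0.1, 1), 8, 2),
                H = matrix(runif(14, 0.1, 1), 2, 7))
    e0 <- sedObjective(Xi, ini)
    expect_lt(sedObjective(Xi, runHALS(Xi, ini,
                convergenceControl(maxIter = 25))), e0)
    expect_lt(sedObjective(Xi, runMU(Xi, ini,
                convergenceControl(maxIter = 25))), e0)
  }
})

test_that("engines reject invalid starting points", {
  X <- randomPlanted(6, 5, 2, seed = 47)
  expect_error(runHALS(X, list(W = matrix(-1, 6, 2),
                               H = matrix(1, 2, 5))), "nonnegative")
  expect_error(runHALS(X, list(W = matrix(1, 6, 3),
                               H = matrix(1, 2, 5))), "incompatible")
})
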