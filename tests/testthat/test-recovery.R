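fx <- fixture2x2()

test_that("an exact factorization yields unit generalized singular values", {
  set.seed(51)
  W0 <- matrix(runif(12), 6, 2); H0 <- matrix(runif(10), 2, 5)
  X <- W0 %*% H0
  pr <- proposeDirections(truncatedSVD(X, 2), W0, H0, 1)
  expect_true(all(abs(pr$lambda[is.finite(pr$lambda)] - 1) < 1e-8))
})

test_that("the 2x2 direction closes the gap to the data exactly", {
  sv <- truncatedSVD(fx$X, 2)
  pr <- proposeDirections(sv, fx$W0, fx$H0, 1)
  fit <- solveDirectNNLS(fx$X, fx$W0, fx$H0, pr$Y, nonneg = FALSE)
  expect_lt(sqrt(fit$objective) / norm(fx$X, "F"), 1e-8)
})

test_that("proposed directions match the generalized-eigen oracle", {
  set.seed(52)
  for (i in 1:20) {
    X <- randomPlanted(30, 20, 5)
    f0 <- underCompleteFit(X, 4, seed = i)
    sv <- truncatedSVD(X, 4)
    pr <- proposeDirections(sv, basisMatrix(f0), coefMatrix(f0), 4)
    B <- fitted(f0)
    A2 <- crossprod(sv@U, B) %*% sv@V
    o <- generalizedEigenOracle(diag(sv@sigma^2, 4), crossprod(A2))
    ov <- o$values
    expect_lt(max(abs(lamScale(pr$lambda) - lamScale(ov))), 1e-8)
    # eigenvector alignment where eigenvalues are well separated
    for (j in which(is.finite(ov))) {
      gap <- min(abs(ov[j] - ov[-j]) / max(ov[j], 1e-12))
      if (gap < 1e-3) next
      yo <- sv@V %*% o$vectors[, j]
      cosine <- abs(sum(pr$Yall[j, ] * yo)) /
        (sqrt(sum(pr$Yall[j, ]^2)) * sqrt(sum(yo^2)))
      expect_gt(cosine, 1 - 1e-6)
    }
  }
  expect_error(proposeDirections(truncatedSVD(diag(2), 1),
                                 matrix(1, 2, 1), matrix(1, 1, 2), 1),
               "rank")
})

test_that("direction rows are sign-resolved against the residual", {
  set.seed(53)
  X <- randomPlanted(8, 6, 3)
  f0 <- underCompleteFit(X, 2, seed = 3)
  W0 <- basisMatrix(f0); H0 <- coefMatrix(f0)
  y <- runif(6)
  expect_equal(truncateDirectionRows(matrix(y, 1), X, W0, H0),
               matrix(y, 1))
  expect_equal(truncateDirectionRows(matrix(-y, 1), X, W0, H0),
               matrix(y, 1))
  DeltaX <- pmax(X - W0 %*% H0, 0)
  for (i in 1:20) {
    ym <- rnorm(6)
    got <- truncateDirectionRows(rbind(ym), X, W0, H0)
    pos <- sum(abs(DeltaX %*% pmax(ym, 0)))
    neg <- sum(abs(DeltaX %*% pmax(-ym, 0)))
    want <- if (pos >= neg) pmax(ym, 0) else pmax(-ym, 0)
    expect_equal(as.vector(got), want)
  }
})

test_that("direct solve is exact: S = 0, alpha = 1 on exact input, and it
           matches a materialized NNLS oracle", {
  set.seed(54)
  W0 <- matrix(runif(12), 6, 2); H0 <- matrix(runif(10), 2, 5)
  X <- W0 %*% H0
  Ynn <- truncateDirectionRows(
    proposeDirections(truncatedSVD(X, 2), W0, H0, 1)$Y, X, W0, H0)
  fit <- solveDirectNNLS(X, W0, H0, Ynn)
  expect_lt(max(abs(fit$S)), 1e-8)
  expect_equal(fit$alpha, c(1, 1), tolerance = 1e-8)

  # random instance: objective matches the dense oracle built here
  X2 <- randomPlanted(6, 5, 3, seed = 55)
  f0 <- underCompleteFit(X2, 2, seed = 5)
  W2 <- basisMatrix(f0); H2 <- coefMatrix(f0)
  Y2 <- truncateDirectionRows(
    proposeDirections(truncatedSVD(X2, 2), W2, H2, 1)$Y, X2, W2, H2)
  fit2 <- solveDirectNNLS(X2, W2, H2, Y2)
  Faug <- cbind(kronecker(t(Y2), diag(1, 6)),
                vapply(1:2, function(p) as.vector(outer(W2[, p], H2[p, ])),
                       numeric(30)))
  oracle <- pracma::lsqnonneg(Faug, as.vector(X2))
  expect_equal(fit2$objective,
               sum((as.vector(X2) - Faug %*% oracle$x)^2),
               tolerance = 1e-8)
  # embedding feasibility: no worse than keeping the old solution
  expect_lte(fit2$objective, sum((X2 - W2 %*% H2)^2) + 1e-10)
  expect_error(solveDirectNNLS(X2, W2, H2, Y2, maxElements = 10),
               "maxElements")
})

test_that("decoupled solve agrees with the direct solve when its S is
           nonnegative, and its reduced Hessian is PSD", {
  set.seed(56)
  for (i in 1:15) {
    X <- randomPlanted(8, 7, 3, seed = 500 + i)
    f0 <- underCompleteFit(X, 2, seed = i)
    W0 <- basisMatrix(f0); H0 <- coefMatrix(f0)
    Ynn <- truncateDirectionRows(
      proposeDirections(truncatedSVD(X, 2), W0, H0, 1)$Y, X, W0, H0)
    dd <- solveDecoupled(X, W0, H0, Ynn)
    expect_gte(min(eigen(dd$reducedHessian, symmetric = TRUE,
                         only.values = TRUE)$values),
               -1e-8 * max(abs(dd$reducedHessian)))
  }
  agree <- 0
  for (i in 1:10) {
    inst <- disjointMissing(seed = 560 + i)
    Ynn <- truncateDirectionRows(
      proposeDirections(truncatedSVD(inst$X, 2), inst$W0, inst$H0, 1)$Y,
      inst$X, inst$W0, inst$H0)
    dd <- solveDecoupled(inst$X, inst$W0, inst$H0, Ynn)
    if (!all(dd$S >= 0)) next
    di <- solveDirectNNLS(inst$X, inst$W0, inst$H0, Ynn)
    expect_lt(abs(dd$objective - di$objective),
              1e-6 * max(1, di$objective))
    agree <- agree + 1
  }
  expect_gt(agree, 0)
  # exact input: S = 0, alpha = 1
  W0 <- matrix(runif(12), 6, 2); H0 <- matrix(runif(10), 2, 5)
  X <- W0 %*% H0
  Ynn <- truncateDirectionRows(
    proposeDirections(truncatedSVD(X, 2), W0, H0, 1)$Y, X, W0, H0)
  dd <- solveDecoupled(X, W0, H0, Ynn)
  expect_lt(max(abs(dd$S)), 1e-8)
  expect_equal(dd$alpha, c(1, 1), tolerance = 1e-8)
  # degenerate directions are named
  expect_error(solveDecoupled(X, W0, H0, rbind(Ynn, Ynn)), "degenerate")
})

test_that("rank-1 pair truncation keeps the dominant nonnegative section", {
  s <- c(1, 2, 0); y <- c(0.5, 1)
  tp <- nndsvdTruncatePairs(cbind(s), rbind(y))
  expect_equal(tp$Wnew %*% tp$Hnew, cbind(s) %*% rbind(y),
               tolerance = 1e-12)
  tn <- nndsvdTruncatePairs(cbind(-s), rbind(-y))
  expect_equal(tn$Wnew %*% tn$Hnew, cbind(s) %*% rbind(y),
               tolerance = 1e-12)
  set.seed(57)
  for (i in 1:20) {
    s <- rnorm(7); y <- rnorm(5)
    tp <- nndsvdTruncatePairs(cbind(s), rbind(y))
    mp <- sqrt(sum(pmax(s, 0)^2)) * sqrt(sum(pmax(y, 0)^2))
    mn <- sqrt(sum(pmax(-s, 0)^2)) * sqrt(sum(pmax(-y, 0)^2))
    keptPos <- all(tp$Wnew[s < 0] == 0)
    expect_equal(keptPos, mp >= mn)
  }
  tz <- nndsvdTruncatePairs(cbind(c(0, 0)), rbind(c(1, 1)))
  expect_equal(tz$zeroPairs, 1L)
})

test_that("amplitude rebalancing solves the Gram NNLS problem", {
  set.seed(58)
  W <- matrix(runif(32), 8, 4); H <- matrix(runif(24), 4, 6)
  X <- W %*% H
  expect_equal(rebalanceAmplitudes(X, W, H), rep(1, 4), tolerance = 1e-8)
  # random instance vs materialized oracle
  X2 <- randomPlanted(8, 6, 4, seed = 59)
  beta <- rebalanceAmplitudes(X2, W, H)
  D <- vapply(1:4, function(p) as.vector(outer(W[, p], H[p, ])),
              numeric(48))
  ref <- pracma::lsqnonneg(D, as.vector(X2))$x
  expect_equal(sum((as.vector(X2) - D %*% beta)^2),
               sum((as.vector(X2) - D %*% ref)^2), tolerance = 1e-8)
  # duplicated component: deterministic representative
  Wd <- cbind(W[, 1], W[, 1]); Hd <- rbind(H[1, ], H[1, ])
  b1 <- rebalanceAmplitudes(X2, Wd, Hd)
  expect_identical(b1, rebalanceAmplitudes(X2, Wd, Hd))
  # all-zero component gets beta = 0
  Wz <- cbind(W, 0); Hz <- rbind(H, 0)
  expect_equal(rebalanceAmplitudes(X2, Wz, Hz)[5], 0)
})

test_that("feature recovery never increases the error and strictly
           improves imperfect factorizations", {
  # the printed 2x2 pair improves strictly
  e0 <- relErr(fx$X, fx$W0, fx$H0)
  rec <- gsvdFeatureRecovery(fx$X, fx$W0, fx$H0, k = 1)
  expect_lt(relErr(fx$X, rec@Wg, rec@Hg), e0)
  # exact input: error unchanged, new components zero, flagged
  set.seed(60)
  W0 <- matrix(runif(12), 6, 2); H0 <- matrix(runif(10), 2, 5)
  X <- W0 %*% H0
  rec0 <- gsvdFeatureRecovery(X, W0, H0, k = 1)
  expect_true(rec0@nothingToRecover)
  expect_true(all(rec0@Wnew == 0))
  expect_equal(relErr(X, rec0@Wg, rec0@Hg), relErr(X, W0, H0))
  expect_error(gsvdFeatureRecovery(X, W0[, 1, drop = FALSE],
                                   H0[1, , drop = FALSE], 1), "rank")
})

test_that("recovery is scale covariant", {
  set.seed(61)
  X <- randomPlanted(12, 10, 4)
  f0 <- underCompleteFit(X, 3, seed = 6)
  r1 <- gsvdFeatureRecovery(X, basisMatrix(f0), coefMatrix(f0), k = 1)
  r2 <- gsvdFeatureRecovery(10 * X, 10 * basisMatrix(f0), coefMatrix(f0),
                            k = 1)
  expect_equal(relErr(X, r1@Wg, r1@Hg),
               relErr(10 * X, r2@Wg, r2@Hg), tolerance = 1e-8)
  expect_equal(10 * r1@Wg %*% r1@Hg, r2@Wg %*% r2@Hg, tolerance = 1e-6)
})

test_that("recovery costs no more than a few HALS sweeps at scale", {
  set.seed(62)
  X <- randomPlanted(220, 210, 9, noise = 0.1)
  f0 <- underCompleteFit(X, 8, seed = 1, maxIter = 30)
  # median per-iteration HALS time over a short timed run
  t0 <- proc.time()[["elapsed"]]
  invisible(runHALS(X, f0, convergenceControl(eps = 1e-15, maxIter = 20)))
  iterTime <- (proc.time()[["elapsed"]] - t0) / 20
  sv <- truncatedSVD(X, 8)
  t1 <- proc.time()[["elapsed"]]
  invisible(gsvdFeatureRecovery(X, basisMatrix(f0), coefMatrix(f0),
                                k = 2, svd = sv))
  recTime <- proc.time()[["elapsed"]] - t1
  expect_lt(recTime, 5 * iterTime + 0.05)
})
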