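# Shared generators for randomized test instances.

# Random nonnegative matrix with a planted low-rank structure plus a small
# uniform noise floor.
randomPlanted <- function(m, n, r, noise = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(runif(m * r), m, r)
  H <- matrix(runif(r * n), r, n)
  W %*% H + matrix(runif(m * n, 0, noise), m, n)
}

# A partially optimized under-complete factorization of X: a few HALS
# sweeps from a random start, the situation feature recovery is meant for.
underCompleteFit <- function(X, r0, seed = 1L, eps = 1e-3,
                             maxIter = 200L) {
  runHALS(X, randomInit(X, r0, seed = seed),
          convergenceControl(eps = eps, maxIter = maxIter))
}

# Random symmetric positive definite matrix.
randomSPD <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) + diag(0.1, p)
}

relErr <- function(X, W, H) relativeFittingError(X, list(W = W, H = H))

# Map generalized singular values onto [0, 1] via lambda / (1 + lambda):
# equivalent to a relative comparison for moderate lambda and stable for
# near-infinite ones, where two algebraically different routes only agree
# to square-root precision on lambda itself.
lamScale <- function(l) ifelse(is.infinite(l), 1, l / (1 + l))

# Instance whose missing component lives on support disjoint from the
# existing factorization: the joint (S, alpha) fit then decouples and the
# unconstrained S equals the nonnegative missing loading exactly.
disjointMissing <- function(seed, m = 9, n = 8, r0 = 2, mSplit = 6,
                            nSplit = 5) {
  set.seed(seed)
  W0 <- rbind(matrix(runif(mSplit * r0, 0.2, 1), mSplit, r0),
              matrix(0, m - mSplit, r0))
  H0 <- cbind(matrix(runif(r0 * nSplit, 0.2, 1), r0, nSplit),
              matrix(0, r0, n - nSplit))
  s <- c(rep(0, mSplit), runif(m - mSplit, 0.3, 1))
  y <- c(rep(0, nSplit), runif(n - nSplit, 0.3, 1))
  list(X = W0 %*% H0 + s %o% y, W0 = W0, H0 = H0)
}
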