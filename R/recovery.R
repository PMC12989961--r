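#' Propose missing coefficient directions by GSVD
#'
#' Compares the rank-r0 truncated SVD of the data against an existing
#' rank-r0 nonnegative factorization B = W0 H0 by taking the GSVD of the
#' pair (\eqn{\Sigma_{r0}}, \eqn{U_{r0}^T B V_{r0}}). Directions where the
#' generalized singular value is large (or infinite) carry energy present
#' in the SVD but missing from the NMF; the top k of them are returned as
#' candidate coefficient rows \eqn{y_i^T = (V_{r0} (Q^T)^{-1} z_i)^T},
#' each normalized to unit 2-norm.
#'
#' @param svd a [TruncatedSVD-class] of the data at rank r0 >= 2.
#' @param W0,H0 the existing nonnegative factors (m x r0 and r0 x n).
#' @param k number of directions to return (1 <= k <= r0).
#' @return list with \code{Y} (k x n matrix, rows ordered by descending
#'   generalized singular value, infinite first), \code{lambdaSelected}
#'   (length k), \code{lambda} (full length-r0 spectrum, useful for
#'   diagnosing how many components are missing) and \code{Yall}
#'   (all r0 candidate rows in spectrum order).
#' @export
proposeDirections <- function(svd, W0, H0, k = 1L) {
  stopifnot(is(svd, "TruncatedSVD"))
  W0 <- .asDenseMatrix(W0)
  H0 <- .asDenseMatrix(H0)
  r0 <- svd@rank
  if (r0 < 2L)
    stop("direction proposal requires rank r0 >= 2 ",
         "(a rank-1 NMF already matches the leading SVD component)",
         call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > r0)
    stop("'k' must satisfy 1 <= k <= r0", call. = FALSE)
  if (ncol(W0) != r0 || nrow(H0) != r0)
    stop("W0/H0 rank must match the truncation rank of 'svd'",
         call. = FALSE)
  A2 <- crossprod(svd@U, W0) %*% (H0 %*% svd@V)     # U' (W0 H0) V, r0 x r0
  g <- gsvdPair(diag(svd@sigma, r0), A2)
  Yhat <- svd@V %*% t(solve(g@Q))                   # columns V (Q')^{-1} z_i
  nrm <- sqrt(colSums(Yhat^2))
  Yall <- t(sweep(Yhat, 2, pmax(nrm, .Machine$double.xmin), "/"))
  list(Y = Yall[seq_len(k), , drop = FALSE],
       lambdaSelected = g@lambda[seq_len(k)],
       lambda = g@lambda,
       Yall = Yall)
}

#' Resolve direction signs against the nonnegative residual
#'
#' A proposed direction is only defined up to sign. For each row y of
#' \code{Y}, both nonnegative truncations \code{max(y, 0)} and
#' \code{max(-y, 0)} are scored by their alignment with the nonnegative
#' residual \eqn{\Delta X = \max(X - W_0 H_0, 0)}, measured as the 1-norm
#' of \eqn{\Delta X \cdot y^+}; the better-aligned truncation is kept.
#'
#' @param Y k x n matrix of candidate rows.
#' @param X,W0,H0 data and existing factors.
#' @param deltaX optional precomputed nonnegative residual
#'   \code{pmax(X - W0 H0, 0)} (recomputed when NULL).
#' @return k x n nonnegative matrix. Rows that truncate to all zeros are
#'   returned as such with attribute \code{"zeroRows"} listing them (the
#'   caller substitutes a fallback direction).
#' @export
truncateDirectionRows <- function(Y, X, W0, H0, deltaX = NULL) {
  Y <- .asDenseMatrix(Y)
  X <- .asDenseMatrix(X)
  DeltaX <- if (is.null(deltaX)) pmax(X - W0 %*% H0, 0) else deltaX
  Yp <- Y; Yp[Yp < 0] <- 0                  # positive parts, rowwise
  Yn <- Yp - Y                              # negative parts
  # DeltaX and the truncations are nonnegative, so the 1-norms of the
  # matrix-vector products are plain column sums of one product each
  scoreP <- colSums(DeltaX %*% t(Yp))
  scoreN <- colSums(DeltaX %*% t(Yn))
  usePos <- scoreP >= scoreN
  out <- ifelse(matrix(usePos, nrow(Y), ncol(Y)), Yp, Yn)
  zero <- which(rowSums(out) == 0)
  if (length(zero)) attr(out, "zeroRows") <- zero
  out
}

#' Direct joint solve for new loadings and old amplitudes
#'
#' Reference solver for the joint problem
#' \eqn{\min \|X - \sum_p \alpha_p w_{0p} h_{0p}^T - S Y\|_F^2} by
#' materializing the full design matrix (the Kronecker operator
#' \eqn{Y^T \otimes I_m} for the flattened S, plus one rank-one regressor
#' per old component for \eqn{\alpha}) and solving the resulting least
#' squares problem, nonnegatively by default. Exact but expensive
#' (forming the design is O(m^2 n k)); the pipeline default is
#' [solveDecoupled()].
#'
#' @param X,W0,H0 data and existing factors.
#' @param Ynn k x n nonnegative direction rows (see
#'   [truncateDirectionRows()]).
#' @param nonneg constrain both S and alpha to be nonnegative (TRUE, the
#'   NNLS formulation); FALSE gives the unconstrained least-squares fit.
#' @param maxElements refuse to materialize a design larger than this many
#'   elements.
#' @return list with \code{S} (m x k), \code{alpha} (length r0) and
#'   \code{objective} (the attained squared Frobenius error).
#' @export
solveDirectNNLS <- function(X, W0, H0, Ynn, nonneg = TRUE,
                            maxElements = 5e7) {
  X <- .asDenseMatrix(X)
  W0 <- .asDenseMatrix(W0)
  H0 <- .asDenseMatrix(H0)
  Ynn <- .asDenseMatrix(Ynn)
  m <- nrow(X); n <- ncol(X)
  r0 <- ncol(W0); k <- nrow(Ynn)
  sz <- as.numeric(m) * n * (as.numeric(m) * k + r0)
  if (sz > maxElements)
    stop("materializing the direct design needs ", format(sz, digits = 3),
         " elements (> maxElements = ", format(maxElements, digits = 3),
         "); use solveDecoupled() or raise the budget", call. = FALSE)
  Fk <- kronecker(t(Ynn), diag(1, m))               # mn x mk
  Fa <- vapply(seq_len(r0),
               function(p) as.vector(outer(W0[, p], H0[p, ])),
               numeric(m * n))
  Faug <- cbind(Fk, Fa)
  xv <- as.vector(X)
  theta <- if (nonneg) {
    pracma::lsqnonneg(Faug, xv)$x
  } else {
    stats::lm.fit(Faug, xv)$coefficients
  }
  theta[is.na(theta)] <- 0
  S <- matrix(theta[seq_len(m * k)], m, k)
  alpha <- theta[m * k + seq_len(r0)]
  list(S = S, alpha = alpha,
       objective = .frob2(X - matrix(Faug %*% theta, m, n)))
}

#' Decoupled solve for new loadings and old amplitudes
#'
#' Fast equivalent of the joint fit: eliminates the flattened loadings S in
#' closed form (their stationary condition against the block operator
#' \eqn{\Psi = Y Y^T \otimes I_m}, applied implicitly through k x k
#' solves) and reduces the problem to a small convex nonnegative quadratic
#' in \eqn{\alpha} with Hessian \eqn{\Theta - P \Psi^{-1} P^T}, where
#' \eqn{\Theta = W_0^T W_0 \odot H_0 H_0^T}. S is then recovered from
#' \eqn{\alpha}; it is unconstrained at this stage and may contain
#' negatives (handled downstream by the pair truncation).
#'
#' @inheritParams solveDirectNNLS
#' @return list with \code{S} (m x k), \code{alpha} (length r0, >= 0),
#'   \code{objective}, and \code{reducedHessian} (the r0 x r0 quadratic
#'   coefficient matrix, positive semidefinite).
#' @export
solveDecoupled <- function(X, W0, H0, Ynn) {
  X <- .asDenseMatrix(X)
  W0 <- .asDenseMatrix(W0)
  H0 <- .asDenseMatrix(H0)
  Ynn <- .asDenseMatrix(Ynn)
  k <- nrow(Ynn)
  YYt <- tcrossprod(Ynn)
  rc <- rcond(YYt)
  if (!is.finite(rc) || rc < 1e-10) {
    rn <- sqrt(rowSums(Ynn^2))
    bad <- which(rn == 0 | duplicated(round(Ynn / pmax(rn, 1e-300), 12)))
    stop("degenerate directions: Y Y' is numerically singular",
         if (length(bad)) paste0(" (suspect rows: ",
                                 paste(bad, collapse = ", "), ")") else "",
         call. = FALSE)
  }
  Ginv <- solve(YYt)
  A <- H0 %*% t(Ynn)                               # r0 x k
  WtW <- crossprod(W0)
  Theta <- WtW * tcrossprod(H0)
  XHt <- X %*% t(H0)
  xi <- colSums(W0 * XHt)                          # xi_p = w0p' X h0p
  XYt <- X %*% t(Ynn)                              # m x k  (the gamma blocks)
  Gm <- XYt %*% Ginv                               # Psi^{-1} gamma
  PPsiPt <- WtW * (A %*% Ginv %*% t(A))
  Ared <- (Theta - PPsiPt + t(Theta - PPsiPt)) / 2
  b <- xi - rowSums(A * crossprod(W0, Gm))         # xi - P Psi^{-1} gamma
  alpha <- nnlsGram(Ared, b)
  S <- (XYt - W0 %*% (alpha * A)) %*% Ginv         # m = Psi^{-1}(gamma - P'alpha)
  # objective through the expanded quadratic (avoids an m x n reconstruction)
  phi <- sum(X * X)
  gTm <- sum(XYt * S)
  aPm <- sum(alpha * rowSums(A * crossprod(W0, S)))
  mPsim <- sum((S %*% YYt) * S)
  obj <- drop(alpha %*% Theta %*% alpha) - 2 * sum(xi * alpha) + phi -
    2 * gTm + 2 * aPm + mPsim
  list(S = S, alpha = alpha, objective = max(obj, 0),
       reducedHessian = Ared, xi = xi)
}

#' Nonnegative truncation of proposed rank-1 pairs
#'
#' For each new component pair (s_p, y_p), splits both vectors into
#' positive and negative sections, keeps the section pair with the larger
#' product of Euclidean norms, and rescales the kept sections so that
#' their norm product carries the section's share of the original pair's
#' energy (the NNDSVD truncation convention). Any remaining scale freedom
#' is absorbed later by the amplitude rebalancing.
#'
#' @param S m x k matrix of loading columns (may contain negatives).
#' @param Y k x n matrix of coefficient rows.
#' @return list with nonnegative \code{Wnew} (m x k) and \code{Hnew}
#'   (k x n), plus \code{zeroPairs}: indices of pairs that truncated to
#'   exactly zero (flagged, not fatal; cannot occur when the residual is
#'   nonzero).
#' @export
nndsvdTruncatePairs <- function(S, Y) {
  S <- .asDenseMatrix(S)
  Y <- .asDenseMatrix(Y)
  k <- ncol(S)
  if (nrow(Y) != k)
    stop("'S' must have one column per row of 'Y'", call. = FALSE)
  Wnew <- matrix(0, nrow(S), k)
  Hnew <- matrix(0, k, ncol(Y))
  zero <- integer(0)
  for (p in seq_len(k)) {
    ns <- sqrt(sum(S[, p]^2)); ny <- sqrt(sum(Y[p, ]^2))
    if (ns == 0 || ny == 0) {
      zero <- c(zero, p)
      next
    }
    tp <- .truncatePair(S[, p] / ns, Y[p, ] / ny)
    if (tp$mu == 0) {
      zero <- c(zero, p)
      next
    }
    scl <- sqrt(ns * ny * tp$mu)
    Wnew[, p] <- scl * tp$u
    Hnew[p, ] <- scl * tp$v
  }
  list(Wnew = Wnew, Hnew = Hnew, zeroPairs = zero)
}

#' Rebalance component amplitudes by nonnegative least squares
#'
#' Given assembled factors W (columns w_p) and H (rows h_p), finds
#' \eqn{\beta \ge 0} minimizing
#' \eqn{\|X - \sum_p \beta_p w_p h_p^T\|_F^2}. The problem is solved on
#' its (r0+k)-dimensional Gram system
#' \eqn{G = W^T W \odot H H^T}, \eqn{b_p = w_p^T X h_p}. An all-zero
#' component gets \eqn{\beta_p = 0} by convention.
#'
#' @param X data matrix.
#' @param W,H nonnegative factors, m x (r0+k) and (r0+k) x n.
#' @return numeric nonnegative vector beta of length r0+k.
#' @export
rebalanceAmplitudes <- function(X, W, H) {
  X <- .asDenseMatrix(X)
  W <- .asDenseMatrix(W)
  H <- .asDenseMatrix(H)
  .checkShapes(X, W, H)
  .checkNonnegative(W, "W")
  .checkNonnegative(H, "H")
  G <- crossprod(W) * tcrossprod(H)
  b <- colSums(W * (X %*% t(H)))
  nnlsGram(G, b)
}

#' GSVD-based feature recovery (one-shot rank expansion)
#'
#' Expands an existing rank-r0 nonnegative factorization by k components:
#' proposes missing coefficient directions from the GSVD of the projected
#' (SVD, NMF) pair, resolves their signs against the nonnegative residual,
#' jointly fits new loading columns S and old-component amplitudes
#' \eqn{\alpha}, truncates each new rank-1 pair to its dominant nonnegative
#' section, and rebalances all r0+k amplitudes by NNLS. The final error
#' never exceeds that of the input factorization, and strictly decreases
#' whenever the input leaves a nonzero residual.
#'
#' If a proposed direction truncates to all zeros, the next-ranked
#' direction from the generalized singular value spectrum is substituted;
#' if all are exhausted, a single-entry direction at the largest positive
#' residual entry is used (which always reduces the error when the
#' residual is nonzero).
#'
#' @param X nonnegative data matrix.
#' @param W0,H0 existing nonnegative factors of rank r0 >= 2.
#' @param k number of components to add (>= 1).
#' @param svd optional precomputed [truncatedSVD()] of X at rank r0
#'   (computed if missing).
#' @param solver \code{"decoupled"} (default) or \code{"direct"}.
#' @return a [RecoveryProposal-class]; slot \code{Wg}/\code{Hg} hold the
#'   augmented rank-(r0+k) factors.
#' @examples
#' fx <- fixture2x2()
#' rec <- gsvdFeatureRecovery(fx$X, fx$W0, fx$H0, k = 1)
#' relativeFittingError(fx$X, list(W = rec@Wg, H = rec@Hg))
#' @export
gsvdFeatureRecovery <- function(X, W0, H0, k = 1L, svd = NULL,
                                solver = c("decoupled", "direct")) {
  solver <- match.arg(solver)
  X <- .asDenseMatrix(X)
  W0 <- .asDenseMatrix(W0)
  H0 <- .asDenseMatrix(H0)
  .checkShapes(X, W0, H0)
  r0 <- ncol(W0)
  k <- as.integer(k)
  if (r0 < 2L)
    stop("feature recovery requires an existing rank of at least 2",
         call. = FALSE)
  if (k < 1L) stop("'k' must be at least 1", call. = FALSE)
  m <- nrow(X); n <- ncol(X)
  logs <- character()

  resid <- X - W0 %*% H0
  normX <- sqrt(.frob2(X))
  if (sqrt(.frob2(resid)) <= 1e-12 * normX) {
    Wg <- cbind(W0, matrix(0, m, k))
    Hg <- rbind(H0, matrix(0, k, n))
    return(new("RecoveryProposal",
               Y = matrix(0, k, n), S = matrix(0, m, k),
               alpha = rep(1, r0), Wnew = matrix(0, m, k),
               Hnew = matrix(0, k, n), beta = rep(c(1, 0), c(r0, k)),
               Wg = Wg, Hg = Hg, lambdaSelected = rep(NA_real_, k),
               lambda = numeric(0), nothingToRecover = TRUE,
               log = "residual below working precision; nothing to recover"))
  }

  if (is.null(svd)) svd <- truncatedSVD(X, r0)
  stopifnot(is(svd, "TruncatedSVD"), svd@rank == r0)
  if (k > r0)
    stop("'k' cannot exceed the existing rank r0", call. = FALSE)

  DeltaX <- resid
  DeltaX[DeltaX < 0] <- 0
  prop <- proposeDirections(svd, W0, H0, k)
  Ynn <- truncateDirectionRows(prop$Y, X, W0, H0, deltaX = DeltaX)
  lambdaSel <- prop$lambdaSelected
  zr <- attr(Ynn, "zeroRows")
  if (length(zr)) {
    # substitute next-ranked untried directions, then the residual ansatz
    nextIdx <- k + 1L
    for (p in zr) {
      replaced <- FALSE
      while (nextIdx <= r0) {
        cand <- truncateDirectionRows(prop$Yall[nextIdx, , drop = FALSE],
                                      X, W0, H0, deltaX = DeltaX)
        if (!all(cand == 0)) {
          Ynn[p, ] <- cand
          lambdaSel[p] <- prop$lambda[nextIdx]
          logs <- c(logs, sprintf(
            "direction %d truncated to zero; substituted spectrum direction %d",
            p, nextIdx))
          replaced <- TRUE
          nextIdx <- nextIdx + 1L
          break
        }
        nextIdx <- nextIdx + 1L
      }
      if (!replaced) {
        ij <- arrayInd(which.max(DeltaX), dim(DeltaX))
        Ynn[p, ] <- 0
        Ynn[p, ij[2]] <- 1
        lambdaSel[p] <- NA_real_
        logs <- c(logs, sprintf(
          "direction %d replaced by largest-positive-residual ansatz (column %d)",
          p, ij[2]))
      }
    }
    attr(Ynn, "zeroRows") <- NULL
  }

  sol <- if (solver == "decoupled") solveDecoupled(X, W0, H0, Ynn)
         else solveDirectNNLS(X, W0, H0, Ynn)
  tp <- nndsvdTruncatePairs(sol$S, Ynn)
  if (length(tp$zeroPairs))
    logs <- c(logs, sprintf(
      "new pair(s) %s truncated to zero despite nonzero residual",
      paste(tp$zeroPairs, collapse = ", ")))

  W <- cbind(sweep(W0, 2, sol$alpha, "*"), tp$Wnew)
  H <- rbind(H0, tp$Hnew)
  if (!is.null(sol$xi)) {
    # same Gram NNLS as rebalanceAmplitudes(), with the xi_p = w0p' X h0p
    # terms reused from the solve stage
    G <- crossprod(W) * tcrossprod(H)
    bNew <- rowSums(crossprod(tp$Wnew, X) * tp$Hnew)
    beta <- nnlsGram(G, c(sol$alpha * sol$xi, bNew))
  } else {
    beta <- rebalanceAmplitudes(X, W, H)
  }
  Wg <- sweep(W, 2, beta, "*")
  Hg <- H

  new("RecoveryProposal", Y = Ynn, S = sol$S, alpha = sol$alpha,
      Wnew = tp$Wnew, Hnew = tp$Hnew, beta = beta, Wg = Wg, Hg = Hg,
      lambdaSelected = lambdaSel, lambda = prop$lambda,
      nothingToRecover = FALSE, log = logs)
}
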