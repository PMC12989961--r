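#' Truncated singular value decomposition with a fixed sign convention
#'
#' Computes the rank-\code{r0} SVD of a dense matrix. Signs are made
#' deterministic by requiring, for each column of \code{U}, that the entry
#' of largest magnitude be nonnegative (ties broken by first index), with
#' the matching column of \code{V} flipped accordingly.
#'
#' @param X numeric matrix with finite entries.
#' @param r0 truncation rank, \code{1 <= r0 <= min(dim(X))}.
#' @return a [TruncatedSVD-class] object.
#' @examples
#' s <- truncatedSVD(fixture2x2()$X, 2)
#' s@sigma
#' @export
truncatedSVD <- function(X, r0) {
  X <- .asDenseMatrix(X)
  .checkFinite(X)
  r0 <- as.integer(r0)
  if (length(r0) != 1L || is.na(r0) || r0 < 1L || r0 > min(dim(X)))
    stop("'r0' must satisfy 1 <= r0 <= min(dim(X))", call. = FALSE)
  sv <- svd(X, nu = r0, nv = r0)
  U <- sv$u
  V <- sv$v
  for (j in seq_len(r0)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  new("TruncatedSVD", U = U, sigma = sv$d[seq_len(r0)], V = V, rank = r0)
}

#' Generalized SVD of a square matrix pair
#'
#' Decomposes a pair of r0 x r0 matrices as \eqn{A_1 = M_1 D_1 Q^T},
#' \eqn{A_2 = M_2 D_2 Q^T} with shared invertible \code{Q}, orthogonal
#' \code{M1}, \code{M2} and diagonal \code{D1} (cosines) and \code{D2}
#' (sines). The construction stacks the pair, takes its SVD, and performs
#' an exact cosine-sine split of the orthonormal column blocks: the top
#' block's SVD supplies the cosines, after which the bottom block's columns
#' are exactly orthogonal with norms equal to the sines. This avoids
#' forming the cross-products \eqn{A_i^T A_i}, whose condition number is
#' the square of the pair's.
#'
#' Generalized singular values are \eqn{\lambda_i = d_{1i}^2/d_{2i}^2},
#' returned in descending order with \code{Inf} first. A sine is classified
#' as zero (infinite \eqn{\lambda}) when it falls below \code{1e-12} times
#' the largest sine.
#'
#' @param A1 r0 x r0 diagonal matrix with nonnegative entries (typically
#'   \code{diag(sigma)} from a [truncatedSVD()]).
#' @param A2 r0 x r0 numeric matrix.
#' @return a [GSVDFactorization-class] object.
#' @examples
#' g <- gsvdPair(diag(2), diag(2))
#' g@lambda  # identical pair: both generalized singular values are 1
#' @export
gsvdPair <- function(A1, A2) {
  A1 <- .asDenseMatrix(A1)
  A2 <- .asDenseMatrix(A2)
  if (nrow(A1) != ncol(A1) || !all(dim(A1) == dim(A2)))
    stop("'A1' and 'A2' must be square matrices of the same size",
         call. = FALSE)
  offdiag <- A1; diag(offdiag) <- 0
  if (any(offdiag != 0) || any(diag(A1) < 0))
    stop("'A1' must be diagonal with nonnegative entries", call. = FALSE)
  r0 <- nrow(A1)

  K <- rbind(A1, A2)
  sv <- svd(K)
  d <- sv$d
  if (d[1] == 0 || d[r0] / d[1] < 1e-12)
    stop("degenerate pair: stacked matrix is numerically rank-deficient ",
         "(Q would be singular); smallest/largest stacked singular value = ",
         format(if (d[1] == 0) 0 else d[r0] / d[1], digits = 3),
         call. = FALSE)
  Z1 <- sv$u[seq_len(r0), , drop = FALSE]
  Z2 <- sv$u[r0 + seq_len(r0), , drop = FALSE]

  # CS split: Z1 = M1 C Vc', then (Z2 Vc)'(Z2 Vc) = I - C^2 exactly, so the
  # columns of Z2 Vc are orthogonal with norms equal to the sines.
  cs <- svd(Z1)
  M1 <- cs$u
  cosv <- pmin(cs$d, 1)
  Vc <- cs$v
  Wm <- Z2 %*% Vc
  sines <- sqrt(colSums(Wm^2))

  smax <- max(sines)
  zeroSine <- if (smax == 0) rep(TRUE, r0) else sines < 1e-12 * smax
  M2 <- matrix(0, r0, r0)
  for (j in which(!zeroSine)) M2[, j] <- Wm[, j] / sines[j]
  if (any(zeroSine)) {
    # complete to an orthonormal basis for the zero-sine columns
    nz <- which(!zeroSine)
    base <- if (length(nz)) M2[, nz, drop = FALSE] else NULL
    cand <- qr.Q(qr(cbind(base, diag(r0))))
    M2[, zeroSine] <- cand[, length(nz) + seq_len(sum(zeroSine)),
                           drop = FALSE]
  }

  # A1 = Z1 diag(d) E' = M1 C (Vc' diag(d) E'), so Q = E diag(d) Vc
  Q <- sv$v %*% (d * Vc)

  l <- sum(!zeroSine)
  lambda <- ifelse(zeroSine, Inf, (cosv / pmax(sines, .Machine$double.xmin))^2)
  lambda[zeroSine] <- Inf

  kq <- kappa(Q, exact = TRUE)
  if (!is.finite(kq) || kq > 1e12)
    stop("degenerate pair: shared factor Q has condition number ",
         format(kq, digits = 3), " (> 1e12)", call. = FALSE)

  new("GSVDFactorization", M1 = M1, M2 = M2, Q = Q,
      D1 = diag(cosv, r0), D2 = diag(sines, r0),
      l = as.integer(l), lambda = as.numeric(lambda))
}

#' Dense generalized-eigenvalue oracle for symmetric pairs
#'
#' Solves \eqn{G_1 v = \lambda G_2 v} for a symmetric pair in which the
#' first matrix is positive definite, by whitening against \eqn{G_1} and
#' inverting the resulting spectrum: \eqn{G_2 v = \mu G_1 v} is a regular
#' symmetric-definite pencil, and \eqn{\lambda = 1/\mu} with
#' \eqn{\mu = 0} mapping to \code{Inf} (directions in the null space of
#' \eqn{G_2}). This handles a rank-deficient \eqn{G_2} correctly — its
#' finite eigenvectors need not lie in its range, so whitening against
#' \eqn{G_2} would be wrong. Intended purely as an independent
#' cross-check for [gsvdPair()] and [proposeDirections()] in tests; the
#' main code path never calls it.
#'
#' @param G1 square symmetric positive definite matrix.
#' @param G2 square symmetric positive semidefinite matrix of equal size.
#' @return list with \code{values} (descending; \code{Inf} first) and
#'   \code{vectors} (columns aligned with \code{values}).
#' @export
generalizedEigenOracle <- function(G1, G2) {
  G1 <- .asDenseMatrix(G1)
  G2 <- .asDenseMatrix(G2)
  if (!all(dim(G1) == dim(G2)) || nrow(G1) != ncol(G1))
    stop("'G1' and 'G2' must be square of equal size", call. = FALSE)
  if (max(abs(G1 - t(G1))) > 1e-10 * max(1, max(abs(G1))) ||
      max(abs(G2 - t(G2))) > 1e-10 * max(1, max(abs(G2))))
    stop("inputs must be symmetric", call. = FALSE)
  n <- nrow(G1)
  e1 <- eigen((G1 + t(G1)) / 2, symmetric = TRUE)
  if (min(e1$values) <= max(e1$values) * n * .Machine$double.eps * 64)
    stop("'G1' must be positive definite for the oracle reduction",
         call. = FALSE)
  Wh <- e1$vectors %*% diag(1 / sqrt(e1$values), n)
  M <- t(Wh) %*% ((G2 + t(G2)) / 2) %*% Wh
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)   # mu descending
  mu <- rev(em$values)                            # ascending
  vecs <- Wh %*% em$vectors[, rev(seq_len(n)), drop = FALSE]
  tol <- max(abs(em$values)) * n * .Machine$double.eps * 64
  vals <- ifelse(mu <= tol, Inf, 1 / mu)
  list(values = vals, vectors = vecs)
}
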