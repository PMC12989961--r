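#' @import methods
NULL

#' Truncated singular value decomposition
#'
#' Holds a rank-\code{r0} SVD triple \eqn{X \approx U \Sigma V^T} with
#' orthonormal \code{U}, \code{V} and singular values sorted in descending
#' order. Created by [truncatedSVD()].
#'
#' @slot U numeric matrix, m x r0, orthonormal columns (left singular vectors).
#' @slot sigma numeric vector of length r0, nonnegative, descending.
#' @slot V numeric matrix, n x r0, orthonormal columns (right singular vectors).
#' @slot rank integer, the truncation rank r0.
#'
#' @seealso [truncatedSVD()], [gsvdFeatureRecovery()]
#' @export
setClass("TruncatedSVD",
  representation(U = "matrix", sigma = "numeric", V = "matrix",
                 rank = "integer"),
  validity = function(object) {
    msg <- character()
    r0 <- object@rank
    if (length(r0) != 1L || r0 < 1L)
      msg <- c(msg, "'rank' must be a single positive integer")
    if (ncol(object@U) != r0 || ncol(object@V) != r0 ||
        length(object@sigma) != r0)
      msg <- c(msg, "U, V and sigma must all have 'rank' components")
    if (any(object@sigma < 0))
      msg <- c(msg, "singular values must be nonnegative")
    if (is.unsorted(rev(object@sigma)))
      msg <- c(msg, "singular values must be sorted in descending order")
    if (length(msg)) msg else TRUE
  })

#' Generalized singular value decomposition of a square matrix pair
#'
#' Result of [gsvdPair()] for a pair (A1, A2) of r0 x r0 matrices:
#' \eqn{A_1 = M_1 D_1 Q^T}, \eqn{A_2 = M_2 D_2 Q^T} with unitary
#' \code{M1}, \code{M2}, shared invertible \code{Q}, and diagonal
#' \code{D1} (cosines, descending) and \code{D2} (sines, ascending).
#' The generalized singular values \code{lambda} are the squared ratios
#' \eqn{d_{1i}^2 / d_{2i}^2}, descending, with \code{Inf} marking
#' directions absent from the second matrix (its rank deficiency).
#'
#' @slot M1,M2 numeric r0 x r0 unitary matrices.
#' @slot Q numeric r0 x r0 invertible matrix shared by both factorizations.
#' @slot D1,D2 numeric r0 x r0 diagonal matrices.
#' @slot l integer, numerical rank of the second matrix of the pair.
#' @slot lambda numeric vector of generalized singular values (descending,
#'   \code{Inf} entries first).
#'
#' @export
setClass("GSVDFactorization",
  representation(M1 = "matrix", M2 = "matrix", Q = "matrix",
                 D1 = "matrix", D2 = "matrix", l = "integer",
                 lambda = "numeric"),
  validity = function(object) {
    r0 <- nrow(object@Q)
    dims <- vapply(list(object@M1, object@M2, object@D1, object@D2),
                   function(m) all(dim(m) == c(r0, r0)), logical(1))
    msg <- character()
    if (!all(dims)) msg <- c(msg, "all factors must be square of equal size")
    if (length(object@lambda) != r0)
      msg <- c(msg, "lambda must have one entry per column")
    if (sum(is.infinite(object@lambda)) != r0 - object@l)
      msg <- c(msg, "number of infinite generalized singular values must be r0 - l")
    if (length(msg)) msg else TRUE
  })

#' Nonnegative matrix factorization fit
#'
#' Paired nonnegative factors \code{W} (m x r, components as columns) and
#' \code{H} (r x n, components as rows), with convergence diagnostics and an
#' optional objective trace. Produced by [runHALS()], [runMU()], [runNMF()],
#' [nndsvdInit()], [gsvdNMF()] and [incrementalExpand()].
#'
#' @slot W numeric matrix m x r, nonnegative loadings.
#' @slot H numeric matrix r x n, nonnegative coefficients.
#' @slot objectiveTrace data.frame with columns \code{iteration} and
#'   \code{objective} (empty unless tracing was requested).
#' @slot converged logical flag.
#' @slot iterations integer iteration count.
#' @slot algorithm character label ("hals", "mu", "nndsvd", ...).
#' @slot metadata list of provenance (seeds, tolerances, stage diagnostics).
#'
#' @seealso [basisMatrix()], [coefMatrix()], [nmfRank()],
#'   [relativeFittingError()]
#' @export
setClass("NMFFit",
  representation(W = "matrix", H = "matrix", objectiveTrace = "data.frame",
                 converged = "logical", iterations = "integer",
                 algorithm = "character", metadata = "list"),
  prototype(objectiveTrace = data.frame(iteration = integer(),
                                        objective = numeric()),
            converged = FALSE, iterations = 0L, algorithm = "none",
            metadata = list()),
  validity = function(object) {
    msg <- character()
    if (ncol(object@W) != nrow(object@H))
      msg <- c(msg, "ncol(W) must equal nrow(H)")
    if (any(object@W < 0) || any(object@H < 0))
      msg <- c(msg, "W and H must be elementwise nonnegative")
    if (length(msg)) msg else TRUE
  })

#' Result of the GSVD-based feature-recovery step
#'
#' All intermediates of the one-shot recovery: the proposed (and
#' nonnegativity-truncated) coefficient rows \code{Y}, the fitted loading
#' columns \code{S}, the amplitude rescalers \code{alpha} of the old
#' components, the truncated nonnegative new pair (\code{Wnew},
#' \code{Hnew}), the rebalanced amplitudes \code{beta} and the assembled
#' output factors (\code{Wg}, \code{Hg}). Created by
#' [gsvdFeatureRecovery()].
#'
#' @slot Y numeric k x n matrix of nonnegative proposed coefficient rows
#'   (after sign-resolved truncation against the residual).
#' @slot S numeric m x k matrix of fitted loading columns (may contain
#'   negatives before pair truncation).
#' @slot alpha numeric length-r0 nonnegative amplitude rescalers.
#' @slot Wnew,Hnew nonnegative truncated new components (m x k and k x n).
#' @slot beta numeric length-(r0+k) nonnegative final amplitudes.
#' @slot Wg,Hg assembled output factors, m x (r0+k) and (r0+k) x n.
#' @slot lambdaSelected numeric, the k generalized singular values backing
#'   the chosen directions.
#' @slot lambda numeric, the full length-r0 generalized singular value
#'   spectrum (diagnostic: its large/infinite entries count the directions
#'   the factorization is missing).
#' @slot nothingToRecover logical, TRUE when the input factorization already
#'   reproduces the data to working precision.
#' @slot log character vector of stage notes (degenerate-direction
#'   substitutions, zero truncations).
#'
#' @export
setClass("RecoveryProposal",
  representation(Y = "matrix", S = "matrix", alpha = "numeric",
                 Wnew = "matrix", Hnew = "matrix", beta = "numeric",
                 Wg = "matrix", Hg = "matrix", lambdaSelected = "numeric",
                 lambda = "numeric", nothingToRecover = "logical",
                 log = "character"),
  prototype(nothingToRecover = FALSE, log = character()),
  validity = function(object) {
    msg <- character()
    if (any(object@alpha < 0)) msg <- c(msg, "alpha must be nonnegative")
    if (any(object@beta < 0)) msg <- c(msg, "beta must be nonnegative")
    if (any(object@Wnew < 0) || any(object@Hnew < 0))
      msg <- c(msg, "Wnew and Hnew must be nonnegative")
    if (any(object@Wg < 0) || any(object@Hg < 0))
      msg <- c(msg, "Wg and Hg must be nonnegative")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "TruncatedSVD", function(object) {
  cat(sprintf("TruncatedSVD: %d x %d, rank %d\n",
              nrow(object@U), nrow(object@V), object@rank))
  cat("  sigma:", paste(signif(utils::head(object@sigma, 5), 4),
                        collapse = ", "),
      if (object@rank > 5) "..." else "", "\n")
})

setMethod("show", "GSVDFactorization", function(object) {
  cat(sprintf("GSVDFactorization of a %d x %d pair (rank of second: %d)\n",
              nrow(object@Q), nrow(object@Q), object@l))
  lam <- object@lambda
  cat("  lambda:", paste(signif(utils::head(lam, 6), 4), collapse = ", "),
      if (length(lam) > 6) "..." else "", "\n")
})

setMethod("show", "NMFFit", function(object) {
  cat(sprintf("NMFFit (%s): %d x %d, rank %d\n", object@algorithm,
              nrow(object@W), ncol(object@H), ncol(object@W)))
  cat(sprintf("  iterations: %d, converged: %s\n", object@iterations,
              object@converged))
})

setMethod("show", "RecoveryProposal", function(object) {
  k <- ncol(object@Wnew)
  cat(sprintf("RecoveryProposal: %d new component%s (output rank %d)\n",
              k, if (k == 1) "" else "s", ncol(object@Wg)))
  if (length(object@lambdaSelected))
    cat("  selected lambda:",
        paste(signif(object@lambdaSelected, 4), collapse = ", "), "\n")
  if (object@nothingToRecover)
    cat("  nothing to recover: input factorization is exact\n")
  if (length(object@log))
    cat("  notes:", paste(object@log, collapse = "; "), "\n")
})
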