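#' Nonnegative least squares on a Gram system
#'
#' Active-set (Lawson-Hanson style) solver for
#' \eqn{\min_{x \ge 0} \tfrac12 x^T G x - b^T x}, i.e. nonnegative least
#' squares expressed through the normal equations \eqn{G = C^T C},
#' \eqn{b = C^T d}. Working directly on the Gram system is what the
#' amplitude problems of the recovery step need: their designs are rank-one
#' outer products whose Gram matrices are cheap Hadamard products, while
#' the explicit design would be m*n rows.
#'
#' Variables whose diagonal Gram entry is (numerically) zero correspond to
#' all-zero components and are fixed at 0. Ties in the most-violated-KKT
#' selection are broken by lowest index, making the solution deterministic
#' in degenerate problems (e.g. duplicated components).
#'
#' @param G symmetric positive semidefinite matrix (p x p).
#' @param b numeric vector of length p.
#' @param tol KKT residual tolerance (relative to \code{max(abs(b))}).
#' @param maxIter safeguard on active-set iterations.
#' @return numeric vector x >= 0.
#' @examples
#' C <- matrix(c(1, 0, 1, 1), 2, 2)
#' d <- c(1, -2)
#' nnlsGram(crossprod(C), crossprod(C, d))  # matches constrained lm fit
#' @export
nnlsGram <- function(G, b, tol = 1e-10, maxIter = 10L * length(b) + 50L) {
  G <- .asDenseMatrix(G)
  b <- as.numeric(b)
  p <- length(b)
  if (!all(dim(G) == c(p, p)))
    stop("'G' must be square with size length(b)", call. = FALSE)
  dg <- diag(G)
  alive <- dg > max(dg, 0) * 1e-14
  x <- numeric(p)
  if (!any(alive)) return(x)
  scale <- max(abs(b), .Machine$double.xmin)
  passive <- logical(p)

  solvePassive <- function(pass) {
    idx <- which(pass)
    Gp <- G[idx, idx, drop = FALSE]
    z <- try(solve(Gp, b[idx]), silent = TRUE)
    if (inherits(z, "try-error")) {
      ridge <- sum(diag(Gp)) / length(idx) * 1e-12
      z <- solve(Gp + diag(ridge, length(idx)), b[idx])
    }
    z
  }

  for (iter in seq_len(maxIter)) {
    w <- b - drop(G %*% x)              # negative gradient
    w[passive | !alive] <- -Inf
    j <- which.max(w)
    if (w[j] <= tol * scale) break
    passive[j] <- TRUE
    repeat {
      z <- numeric(p)
      z[passive] <- solvePassive(passive)
      if (all(z[passive] > 0)) {
        x <- z
        break
      }
      viol <- which(passive & z <= 0)
      ratio <- x[viol] / (x[viol] - z[viol])
      a <- min(ratio)
      x <- x + a * (z - x)
      drop0 <- viol[ratio <= a + 1e-15]
      x[drop0] <- 0
      passive[drop0] <- FALSE
      x[x < 0] <- 0
      if (!any(passive)) {
        x[] <- 0
        break
      }
    }
  }
  x
}
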