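#' Convergence control for the NMF engines
#'
#' Bundles the relative tolerance of the per-component convergence
#' criterion, its stage-wise variants for the rank-expansion pipeline, and
#' the iteration cap.
#'
#' The stopping rule monitors the maximum relative change of every column
#' of W and row of H between successive sweeps: iteration stops when
#' \eqn{\|w_j^{(t+1)} - w_j^{(t)}\|^2 \le \epsilon
#' \|w_j^{(t+1)} + w_j^{(t)}\|^2} for all j, and likewise for the rows of
#' H. A component that is identically zero in both iterates counts as
#' converged (an unchanging dead component).
#'
#' @param eps relative tolerance \eqn{\epsilon} (default \code{1e-4}).
#' @param eps0 tolerance for the under-complete stage of the pipeline
#'   (defaults to \code{eps}).
#' @param eps1 tolerance for the final refinement stage (defaults to
#'   \code{eps}).
#' @param maxIter iteration cap (set high so the tolerance, not the cap,
#'   normally terminates).
#' @param traceObjective if TRUE the objective \eqn{\frac12\|X - WH\|_F^2}
#'   is recorded every iteration (off by default: evaluating it costs more
#'   than an update sweep).
#' @return a list of class \code{"convergenceControl"}.
#' @export
convergenceControl <- function(eps = 1e-4, eps0 = eps, eps1 = eps,
                               maxIter = 5000L, traceObjective = FALSE) {
  stopifnot(eps > 0, eps0 > 0, eps1 > 0, maxIter >= 1)
  structure(list(eps = eps, eps0 = eps0, eps1 = eps1,
                 maxIter = as.integer(maxIter),
                 traceObjective = isTRUE(traceObjective)),
            class = "convergenceControl")
}

#' Squared-Euclidean-distance NMF objective
#'
#' \eqn{D_E(W,H;X) = \frac12 \|X - WH\|_F^2}.
#'
#' @param X data matrix.
#' @param fit an [NMFFit-class], or a list with elements \code{W}, \code{H}.
#' @return nonnegative scalar.
#' @export
sedObjective <- function(X, fit) {
  X <- .asDenseMatrix(X)
  W <- if (is(fit, "NMFFit")) fit@W else fit$W
  H <- if (is(fit, "NMFFit")) fit@H else fit$H
  .checkShapes(X, W, H)
  0.5 * .frob2(X - W %*% H)
}

#' Relative fitting error (percent)
#'
#' \eqn{100\,\|X - WH\|_F^2 / \|X\|_F^2}, the quality metric used to
#' compare local optima of different factorization strategies.
#'
#' @inheritParams sedObjective
#' @return percent value in \eqn{[0, \infty)}.
#' @export
relativeFittingError <- function(X, fit) {
  X <- .asDenseMatrix(X)
  W <- if (is(fit, "NMFFit")) fit@W else fit$W
  H <- if (is(fit, "NMFFit")) fit@H else fit$H
  .checkShapes(X, W, H)
  nx <- .frob2(X)
  if (nx == 0)
    stop("relative fitting error is undefined for an all-zero matrix",
         call. = FALSE)
  100 * .frob2(X - W %*% H) / nx
}

#' Per-component convergence test between successive iterates
#'
#' Returns TRUE iff, for every component j, both the column change in W and
#' the row change in H satisfy
#' \eqn{\|\Delta\|^2 \le \epsilon \|\mathrm{sum}\|^2}. A component with
#' zero difference and zero sum (dead in both iterates) counts as
#' converged.
#'
#' @param prev,curr [NMFFit-class] objects (or W/H lists) of equal rank.
#' @param eps relative tolerance.
#' @return logical scalar.
#' @export
nmfConverged <- function(prev, curr, eps) {
  Wp <- if (is(prev, "NMFFit")) prev@W else prev$W
  Hp <- if (is(prev, "NMFFit")) prev@H else prev$H
  Wc <- if (is(curr, "NMFFit")) curr@W else curr$W
  Hc <- if (is(curr, "NMFFit")) curr@H else curr$H
  if (!all(dim(Wp) == dim(Wc)) || !all(dim(Hp) == dim(Hc)))
    stop("factorization ranks/shapes differ", call. = FALSE)
  .colsConverged(Wp, Wc, eps) && .colsConverged(t(Hp), t(Hc), eps)
}

.colsConverged <- function(Aprev, Acurr, eps) {
  dn <- colSums((Acurr - Aprev)^2)
  sn <- colSums((Acurr + Aprev)^2)
  all(dn <= eps * sn | (dn == 0 & sn == 0))
}

#' NNDSVD-family initialization for NMF
#'
#' SVD-based deterministic initialization: each singular triple is split
#' into its positive and negative sections and the section with the larger
#' norm product is kept, scaled to preserve the triple's energy. Variant
#' \code{"a"} replaces the resulting zeros with \code{mean(X)}; variant
#' \code{"ar"} replaces them with uniform draws on
#' \code{[0, mean(X)/100]} from \code{seed}. The plain variant keeps them
#' at zero.
#'
#' @param X nonnegative data matrix.
#' @param r target rank, \code{r <= min(dim(X))}.
#' @param variant one of \code{"plain"}, \code{"a"}, \code{"ar"}.
#' @param seed integer, used only by variant \code{"ar"}.
#' @return an [NMFFit-class] with algorithm \code{"nndsvd"}.
#' @references Boutsidis & Gallopoulos (2008) SVD-based initialization for
#'   NMF, Pattern Recognition 41(4).
#' @export
nndsvdInit <- function(X, r, variant = c("plain", "a", "ar"), seed = 1L) {
  variant <- match.arg(variant)
  X <- .asDenseMatrix(X)
  .checkFinite(X)
  .checkNonnegative(X)
  r <- as.integer(r)
  if (r < 1L || r > min(dim(X)))
    stop("'r' must satisfy 1 <= r <= min(dim(X))", call. = FALSE)
  m <- nrow(X); n <- ncol(X)
  sv <- truncatedSVD(X, r)
  W <- matrix(0, m, r)
  H <- matrix(0, r, n)
  # leading pair of a nonnegative matrix is nonnegative (Perron-Frobenius)
  W[, 1] <- sqrt(sv@sigma[1]) * abs(sv@U[, 1])
  H[1, ] <- sqrt(sv@sigma[1]) * abs(sv@V[, 1])
  if (r >= 2L) {
    for (j in 2:r) {
      tp <- .truncatePair(sv@U[, j], sv@V[, j])
      W[, j] <- sqrt(sv@sigma[j] * tp$mu) * tp$u
      H[j, ] <- sqrt(sv@sigma[j] * tp$mu) * tp$v
    }
  }
  meta <- list(variant = variant)
  if (variant != "plain") {
    fill <- mean(X)
    zw <- W == 0; zh <- H == 0
    if (variant == "a") {
      W[zw] <- fill
      H[zh] <- fill
    } else {
      set.seed(as.integer(seed))
      W[zw] <- stats::runif(sum(zw), 0, fill / 100)
      H[zh] <- stats::runif(sum(zh), 0, fill / 100)
      meta$seed <- as.integer(seed)
    }
  }
  .newFit(W, H, algorithm = "nndsvd", metadata = meta)
}

# Keep the dominant nonnegative section of a rank-1 pair of unit vectors.
# Returns unit-normalized section directions and the norm product mu.
.truncatePair <- function(u, v) {
  up <- pmax(u, 0); un <- pmax(-u, 0)
  vp <- pmax(v, 0); vn <- pmax(-v, 0)
  npu <- sqrt(sum(up^2)); npv <- sqrt(sum(vp^2))
  nnu <- sqrt(sum(un^2)); nnv <- sqrt(sum(vn^2))
  mp <- npu * npv
  mn <- nnu * nnv
  if (mp >= mn) {
    if (mp == 0) return(list(u = up, v = vp, mu = 0))
    list(u = up / npu, v = vp / npv, mu = mp)
  } else {
    list(u = un / nnu, v = vn / nnv, mu = mn)
  }
}

#' Hierarchical alternating least squares (HALS) NMF
#'
#' Cycles through the components in fixed order each sweep, updating the
#' columns of W and then the rows of H by their closed-form nonnegative
#' coordinate minimizers. The objective is non-increasing sweep to sweep.
#' A column update that would zero out a component leaves it at a small
#' uniform level (\code{1e-16 * max(X)}) so it can be revived later.
#'
#' @param X nonnegative data matrix.
#' @param init an [NMFFit-class] (or W/H list) supplying the nonnegative
#'   starting point.
#' @param control a [convergenceControl()] list; \code{control$eps} and
#'   \code{control$maxIter} govern termination.
#' @return an [NMFFit-class] with algorithm \code{"hals"}.
#' @export
runHALS <- function(X, init, control = convergenceControl()) {
  .runEngine(X, init, control, engine = "hals")
}

#' Multiplicative-update (MU) NMF
#'
#' Lee-Seung multiplicative updates for the squared-Euclidean objective,
#' with a small floor (\code{1e-9}) in the denominators. MU cannot revive
#' a component whose entries are exactly zero; when initializing from a
#' truncation-based starting point, add a small positive perturbation
#' first (the pipeline does this automatically, see [gsvdNMF()]).
#'
#' @inheritParams runHALS
#' @return an [NMFFit-class] with algorithm \code{"mu"}.
#' @export
runMU <- function(X, init, control = convergenceControl()) {
  .runEngine(X, init, control, engine = "mu")
}

#' Run an NMF engine by name
#'
#' @inheritParams runHALS
#' @param engine \code{"hals"} or \code{"mu"}.
#' @export
runNMF <- function(X, init, control = convergenceControl(),
                   engine = c("hals", "mu")) {
  engine <- match.arg(engine)
  .runEngine(X, init, control, engine = engine)
}

.runEngine <- function(X, init, control, engine) {
  X <- .asDenseMatrix(X)
  .checkFinite(X)
  W <- if (is(init, "NMFFit")) init@W else .asDenseMatrix(init$W, "init$W")
  H <- if (is(init, "NMFFit")) init@H else .asDenseMatrix(init$H, "init$H")
  .checkShapes(X, W, H)
  .checkNonnegative(W, "init W")
  .checkNonnegative(H, "init H")
  r <- ncol(W)
  eps <- control$eps
  floorW <- 1e-16 * max(X, 0)
  muFloor <- 1e-9
  traceIt <- integer(0)
  traceObj <- numeric(0)
  converged <- FALSE
  iterations <- 0L

  for (it in seq_len(control$maxIter)) {
    Wprev <- W; Hprev <- H
    if (engine == "hals") {
      HHt <- tcrossprod(H)
      XHt <- X %*% t(H)
      for (p in seq_len(r)) {
        den <- HHt[p, p]
        if (den > 0) {
          wp <- pmax(W[, p] + (XHt[, p] - W %*% HHt[, p]) / den, 0)
          if (all(wp == 0)) wp <- rep(floorW, nrow(X))
          W[, p] <- wp
        }
      }
      WtW <- crossprod(W)
      WtX <- crossprod(W, X)
      for (p in seq_len(r)) {
        den <- WtW[p, p]
        if (den > 0) {
          hp <- pmax(H[p, ] + (WtX[p, ] - drop(WtW[p, ] %*% H)) / den, 0)
          if (all(hp == 0)) hp <- rep(floorW, ncol(X))
          H[p, ] <- hp
        }
      }
    } else {
      WtX <- crossprod(W, X)
      WtWH <- crossprod(W) %*% H
      H <- H * WtX / (WtWH + muFloor)
      XHt <- X %*% t(H)
      WHHt <- W %*% tcrossprod(H)
      W <- W * XHt / (WHHt + muFloor)
    }
    if (!all(is.finite(W)) || !all(is.finite(H)))
      stop("non-finite values produced at iteration ", it, call. = FALSE)
    iterations <- it
    if (control$traceObjective) {
      traceIt <- c(traceIt, it)
      traceObj <- c(traceObj, 0.5 * .frob2(X - W %*% H))
    }
    if (.colsConverged(Wprev, W, eps) && .colsConverged(t(Hprev), t(H), eps)) {
      converged <- TRUE
      break
    }
  }
  .newFit(W, H, algorithm = engine, converged = converged,
          iterations = iterations,
          trace = data.frame(iteration = traceIt, objective = traceObj),
          metadata = list(eps = eps, maxIter = control$maxIter))
}
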