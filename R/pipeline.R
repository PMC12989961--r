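#' Resolve the number of components to add
#'
#' Policy \code{"one"} adds a single component; \code{"fraction:0.2"} adds
#' 20\% of the current rank, rounded half away from zero and floored at 1;
#' an integer is used as-is.
#'
#' @param k integer count, or one of \code{"one"}, \code{"fraction:<f>"}.
#' @param r0 current (under-complete) rank.
#' @return positive integer.
#' @examples
#' resolveK("fraction:0.2", 9)  # 2
#' resolveK("fraction:0.2", 2)  # 1
#' @export
resolveK <- function(k, r0) {
  if (is.numeric(k)) {
    k <- as.integer(k)
    if (k < 1L) stop("'k' must be at least 1", call. = FALSE)
    return(k)
  }
  if (identical(k, "one")) return(1L)
  if (is.character(k) && startsWith(k, "fraction:")) {
    f <- as.numeric(sub("^fraction:", "", k))
    if (!is.finite(f) || f <= 0)
      stop("invalid fraction in k policy: ", k, call. = FALSE)
    return(max(1L, as.integer(.roundHalfUp(f * r0))))
  }
  stop("unknown k policy: ", k, call. = FALSE)
}

#' Random nonnegative initialization
#'
#' Entries i.i.d. uniform on \code{[0, sqrt(mean(X)/r)]}, so the expected
#' scale of the product WH matches the data mean.
#'
#' @param X nonnegative data matrix.
#' @param r rank.
#' @param seed integer seed.
#' @return an [NMFFit-class] with algorithm \code{"random"}.
#' @export
randomInit <- function(X, r, seed = 1L) {
  X <- .asDenseMatrix(X)
  r <- as.integer(r)
  set.seed(as.integer(seed))
  hi <- sqrt(max(mean(X), .Machine$double.xmin) / r)
  W <- matrix(stats::runif(nrow(X) * r, 0, hi), nrow(X), r)
  H <- matrix(stats::runif(r * ncol(X), 0, hi), r, ncol(X))
  .newFit(W, H, algorithm = "random",
          metadata = list(seed = as.integer(seed)))
}

.makeInit <- function(X, r, init, seed) {
  if (is(init, "NMFFit") || is.list(init)) {
    W <- if (is(init, "NMFFit")) init@W else init$W
    H <- if (is(init, "NMFFit")) init@H else init$H
    if (ncol(W) != r)
      stop("supplied initialization has rank ", ncol(W),
           " but rank ", r, " was requested", call. = FALSE)
    return(.newFit(W, H, algorithm = "supplied"))
  }
  switch(init,
    random  = randomInit(X, r, seed),
    nndsvd  = nndsvdInit(X, r, "plain"),
    nndsvda = nndsvdInit(X, r, "a"),
    nndsvdar = nndsvdInit(X, r, "ar", seed),
    stop("unknown init: ", init, call. = FALSE))
}

#' GSVD-NMF: rank expansion of an under-complete NMF
#'
#' Full three-stage pipeline: (1) under-complete NMF at rank r0 with
#' tolerance \code{control$eps0}; (2) one-shot GSVD-based feature recovery
#' adding k components; (3) NMF refinement at rank r0+k with tolerance
#' \code{control$eps1}, initialized from the recovered factors. When the
#' engine is MU, a perturbation of \code{1e-5} is added to every entry of
#' the recovered factors before refinement, since multiplicative updates
#' cannot activate exactly-zero entries left by the truncation.
#'
#' @param X nonnegative data matrix.
#' @param r0 under-complete rank (>= 2).
#' @param k components to add: integer, \code{"one"}, or
#'   \code{"fraction:<f>"} (see [resolveK()]).
#' @param engine \code{"hals"} or \code{"mu"}.
#' @param init initialization for stage 1: \code{"nndsvd"},
#'   \code{"nndsvda"}, \code{"nndsvdar"}, \code{"random"}, or an
#'   [NMFFit-class]/list with W, H.
#' @param control a [convergenceControl()] (uses \code{eps0}, \code{eps1},
#'   \code{maxIter}).
#' @param seed seed for random/nndsvdar initialization.
#' @param solver recovery solver, see [gsvdFeatureRecovery()].
#' @return an [NMFFit-class] of rank r0+k; \code{metadata} carries stage
#'   errors (percent), the generalized singular value spectrum, the
#'   recovery log and stage timings.
#' @examples
#' fx <- fixture2x2()
#' fit <- gsvdNMF(fx$X, r0 = 2, k = 1)
#' relativeFittingError(fx$X, fit)  # ~0: rank 3 covers a 2x2 matrix
#' @export
gsvdNMF <- function(X, r0, k = "one", engine = c("hals", "mu"),
                    init = "nndsvd", control = convergenceControl(),
                    seed = 1L, solver = "decoupled") {
  engine <- match.arg(engine)
  X <- .asDenseMatrix(X)
  .checkFinite(X)
  .checkNonnegative(X)
  r0 <- as.integer(r0)
  if (r0 < 2L) stop("'r0' must be at least 2", call. = FALSE)
  kk <- resolveK(k, r0)

  t0 <- proc.time()[["elapsed"]]
  init0 <- .makeInit(X, r0, init, seed)
  ctl0 <- control; ctl0$eps <- control$eps0
  fit0 <- runNMF(X, init0, ctl0, engine = engine)
  t1 <- proc.time()[["elapsed"]]

  sv <- truncatedSVD(X, r0)
  rec <- gsvdFeatureRecovery(X, fit0@W, fit0@H, k = kk, svd = sv,
                             solver = solver)
  t2 <- proc.time()[["elapsed"]]

  Wg <- rec@Wg; Hg <- rec@Hg
  if (engine == "mu") {
    Wg <- Wg + 1e-5
    Hg <- Hg + 1e-5
  }
  ctl1 <- control; ctl1$eps <- control$eps1
  fit1 <- runNMF(X, list(W = Wg, H = Hg), ctl1, engine = engine)
  t3 <- proc.time()[["elapsed"]]

  fit1@metadata <- list(
    r0 = r0, k = kk, engine = engine, seed = as.integer(seed),
    eps0 = control$eps0, eps1 = control$eps1,
    underCompleteError = relativeFittingError(X, fit0),
    recoveryError = relativeFittingError(X, list(W = rec@Wg, H = rec@Hg)),
    finalError = relativeFittingError(X, fit1),
    lambda = rec@lambda,
    lambdaSelected = rec@lambdaSelected,
    nothingToRecover = rec@nothingToRecover,
    recoveryLog = rec@log,
    stage1Iterations = fit0@iterations,
    stage3Iterations = fit1@iterations,
    timings = c(stage1 = t1 - t0, recovery = t2 - t1, stage3 = t3 - t2))
  fit1
}

#' Incremental rank expansion, one component at a time
#'
#' Starts from an NMF at \code{rStart} and repeats (recover one component,
#' refine by NMF) until \code{rTarget} components are reached, recording
#' the relative fitting error after each refinement. The trajectory is
#' non-increasing in rank.
#'
#' @inheritParams gsvdNMF
#' @param rStart starting rank (>= 2).
#' @param rTarget target rank (>= rStart).
#' @return an [NMFFit-class] of rank \code{rTarget}; its
#'   \code{metadata$trajectory} is a data.frame with columns \code{rank}
#'   and \code{error} (percent).
#' @export
incrementalExpand <- function(X, rStart, rTarget, engine = c("hals", "mu"),
                              init = "nndsvd",
                              control = convergenceControl(), seed = 1L,
                              solver = "decoupled") {
  engine <- match.arg(engine)
  X <- .asDenseMatrix(X)
  .checkFinite(X)
  .checkNonnegative(X)
  rStart <- as.integer(rStart); rTarget <- as.integer(rTarget)
  if (rStart < 2L || rTarget < rStart)
    stop("need 2 <= rStart <= rTarget", call. = FALSE)
  ctl <- control; ctl$eps <- control$eps1
  fit <- runNMF(X, .makeInit(X, rStart, init, seed), ctl, engine = engine)
  traj <- data.frame(rank = rStart, error = relativeFittingError(X, fit))
  r <- rStart
  while (r < rTarget) {
    rec <- gsvdFeatureRecovery(X, fit@W, fit@H, k = 1L, solver = solver)
    Wg <- rec@Wg; Hg <- rec@Hg
    if (engine == "mu") { Wg <- Wg + 1e-5; Hg <- Hg + 1e-5 }
    fit <- runNMF(X, list(W = Wg, H = Hg), ctl, engine = engine)
    r <- r + 1L
    traj <- rbind(traj,
                  data.frame(rank = r,
                             error = relativeFittingError(X, fit)))
  }
  fit@metadata <- list(trajectory = traj, engine = engine,
                       seed = as.integer(seed), rStart = rStart,
                       rTarget = rTarget)
  fit
}

#' Paired comparison of rank expansion against restarting NMF
#'
#' For each seed, one random rank-r initialization is drawn. The
#' \code{"standard"} arm runs NMF at rank r directly from it; the
#' \code{"gsvd"} arm runs under-complete NMF from the first
#' \code{r0 = r - k} components of the same initialization (tolerance
#' \code{control$eps0}), then expands by k components and refines
#' (tolerance \code{control$eps1}). The two arms therefore share as much
#' of their initialization as their differing ranks allow.
#'
#' @inheritParams gsvdNMF
#' @param r target rank of both arms.
#' @param nSeeds number of random initializations.
#' @param seeds optional explicit integer seeds (overrides \code{nSeeds}).
#' @return data.frame with one row per (seed, arm): columns \code{seed},
#'   \code{arm}, \code{error} (percent), \code{iterations},
#'   \code{seconds}. Failed seeds are recorded with \code{NA} error.
#' @export
benchmarkCompare <- function(X, r, k = 1L, nSeeds = 10L,
                             engine = c("hals", "mu"),
                             control = convergenceControl(),
                             seeds = NULL, solver = "decoupled") {
  engine <- match.arg(engine)
  X <- .asDenseMatrix(X)
  r <- as.integer(r)
  kk <- resolveK(k, r)
  r0 <- r - kk
  if (r0 < 2L)
    stop("r - k must be at least 2 for the gsvd arm", call. = FALSE)
  if (is.null(seeds)) seeds <- seq_len(as.integer(nSeeds))
  out <- list()
  for (s in seeds) {
    rec <- tryCatch({
      init <- randomInit(X, r, seed = s)
      ctl1 <- control; ctl1$eps <- control$eps1
      tA <- proc.time()[["elapsed"]]
      std <- runNMF(X, init, ctl1, engine = engine)
      tB <- proc.time()[["elapsed"]]
      sub <- list(W = init@W[, seq_len(r0), drop = FALSE],
                  H = init@H[seq_len(r0), , drop = FALSE])
      gf <- gsvdNMF(X, r0 = r0, k = kk, engine = engine, init = sub,
                    control = control, seed = s, solver = solver)
      tC <- proc.time()[["elapsed"]]
      rbind(
        data.frame(seed = s, arm = "standard",
                   error = relativeFittingError(X, std),
                   iterations = std@iterations, seconds = tB - tA),
        data.frame(seed = s, arm = "gsvd",
                   error = gf@metadata$finalError,
                   iterations = gf@metadata$stage1Iterations +
                     gf@metadata$stage3Iterations,
                   seconds = tC - tB))
    }, error = function(e) {
      warning("seed ", s, " failed: ", conditionMessage(e), call. = FALSE)
      data.frame(seed = s, arm = c("standard", "gsvd"), error = NA_real_,
                 iterations = NA_integer_, seconds = NA_real_)
    })
    out[[length(out) + 1L]] <- rec
  }
  do.call(rbind, out)
}
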