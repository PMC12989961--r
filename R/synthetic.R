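#' Specification for the synthetic source-separation scenario
#'
#' Describes a ground truth of smooth, unimodal, nonnegative component
#' profiles in both factors (Gaussian bumps with randomized centers and
#' widths), combined as X = W H plus Gaussian noise scaled relative to the
#' signal RMS. Defaults emulate a ten-source unmixing problem at moderate
#' noise.
#'
#' @param m,n matrix dimensions.
#' @param rTrue number of ground-truth components.
#' @param centerSpread fraction of the axis over which bump centers are
#'   drawn (centered; 0.9 means centers avoid the outer 5\% on each side).
#' @param widthRange bump standard deviations as a fraction of the axis
#'   length, drawn uniformly from this range.
#' @param noiseSigma Gaussian noise scale relative to the signal RMS.
#' @param seed integer seed; the whole generation is deterministic in it.
#' @param clipNegative clip negative entries after noise addition (NMF
#'   needs nonnegative input); recorded in the spec.
#' @param maxCosine admissible pairwise cosine similarity between distinct
#'   components (violators are redrawn).
#' @return a list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(m = 200L, n = 300L, rTrue = 10L,
                          centerSpread = 0.9, widthRange = c(0.02, 0.06),
                          noiseSigma = 0.1, seed = 1L,
                          clipNegative = TRUE, maxCosine = 0.95) {
  stopifnot(m >= 1, n >= 1, rTrue >= 1, rTrue <= min(m, n),
            noiseSigma >= 0, length(widthRange) == 2,
            widthRange[1] > 0, widthRange[2] >= widthRange[1])
  structure(list(m = as.integer(m), n = as.integer(n),
                 rTrue = as.integer(rTrue), centerSpread = centerSpread,
                 widthRange = widthRange, noiseSigma = noiseSigma,
                 seed = as.integer(seed),
                 clipNegative = isTRUE(clipNegative),
                 maxCosine = maxCosine),
            class = "syntheticSpec")
}

.bump <- function(len, center, width, amplitude) {
  t <- seq_len(len)
  amplitude * exp(-(t - center)^2 / (2 * width^2))
}

# Centers are stratified: the admissible region is split into r equal
# strata, one bump per stratum (in shuffled component order), so distinct
# sources occupy distinct positions as in a real unmixing profile; widths
# and amplitudes are free, and any residual near-collinear pair is redrawn.
.drawProfiles <- function(len, r, spread, widthRange, maxCosine,
                          maxTries = 100L) {
  lo <- (1 - spread) / 2
  strata <- sample.int(r)
  P <- matrix(0, len, r)
  for (j in seq_len(r)) {
    ok <- FALSE
    for (tr in seq_len(maxTries)) {
      u <- (strata[j] - 1 + stats::runif(1)) / r
      center <- (lo + spread * u) * len
      width <- stats::runif(1, widthRange[1], widthRange[2]) * len
      amp <- stats::runif(1, 0.5, 1.5)
      cand <- .bump(len, center, width, amp)
      if (sum(cand^2) == 0) next
      if (j == 1L) { ok <- TRUE }
      else {
        prev <- P[, seq_len(j - 1L), drop = FALSE]
        cs <- crossprod(prev, cand) /
          (sqrt(colSums(prev^2)) * sqrt(sum(cand^2)))
        ok <- all(cs < maxCosine)
      }
      if (ok) { P[, j] <- cand; break }
    }
    if (!ok)
      stop("could not draw ", r, " sufficiently distinct profiles in ",
           maxTries, " tries; widen widthRange or lower rTrue",
           call. = FALSE)
  }
  P
}

#' Generate ground-truth nonnegative factors
#'
#' Draws the smooth bump profiles described by a [syntheticSpec()]:
#' columns of W over the row axis and rows of H over the column axis, each
#' with randomized center, width and amplitude, redrawn until all pairwise
#' cosine similarities are below \code{spec$maxCosine}.
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{Wtrue} (m x rTrue) and \code{Htrue} (rTrue x n),
#'   both nonnegative with nonzero component norms.
#' @export
makeGroundTruth <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  set.seed(spec$seed)
  Wtrue <- .drawProfiles(spec$m, spec$rTrue, spec$centerSpread,
                         spec$widthRange, spec$maxCosine)
  Htrue <- t(.drawProfiles(spec$n, spec$rTrue, spec$centerSpread,
                           spec$widthRange, spec$maxCosine))
  list(Wtrue = Wtrue, Htrue = Htrue)
}

#' Assemble a noisy data matrix from ground-truth factors
#'
#' X = Wtrue Htrue + sigma * rms(Wtrue Htrue) * E with E i.i.d. standard
#' normal, optionally clipped at zero.
#'
#' @param Wtrue,Htrue nonnegative factors.
#' @param noiseSigma noise scale relative to the signal RMS.
#' @param seed integer seed for the noise draw.
#' @param clipNegative clip negative entries to zero.
#' @return numeric matrix with attribute \code{"clipped"} (logical).
#' @export
makeMatrix <- function(Wtrue, Htrue, noiseSigma = 0.1, seed = 1L,
                       clipNegative = TRUE) {
  Wtrue <- .asDenseMatrix(Wtrue)
  Htrue <- .asDenseMatrix(Htrue)
  if (ncol(Wtrue) != nrow(Htrue))
    stop("incompatible factor shapes", call. = FALSE)
  stopifnot(noiseSigma >= 0)
  signal <- Wtrue %*% Htrue
  X <- signal
  if (noiseSigma > 0) {
    set.seed(as.integer(seed))
    rms <- sqrt(mean(signal^2))
    X <- X + noiseSigma * rms *
      matrix(stats::rnorm(length(signal)), nrow(signal), ncol(signal))
  }
  if (clipNegative) X <- pmax(X, 0)
  attr(X, "clipped") <- isTRUE(clipNegative)
  X
}

#' One-call synthetic scenario
#'
#' Convenience wrapper: draws ground truth and data from a spec.
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{X}, \code{Wtrue}, \code{Htrue}, \code{spec}.
#' @export
makeSynthetic <- function(spec = syntheticSpec()) {
  gt <- makeGroundTruth(spec)
  X <- makeMatrix(gt$Wtrue, gt$Htrue, spec$noiseSigma,
                  seed = spec$seed + 1000L,
                  clipNegative = spec$clipNegative)
  list(X = X, Wtrue = gt$Wtrue, Htrue = gt$Htrue, spec = spec)
}

#' The printed 2x2 concept fixture
#'
#' The 2x2 data matrix and the deliberately imperfect rank-2 nonnegative
#' factorization used to illustrate GSVD-based feature recovery: the pair
#' (W0, H0) is a relatively poor approximation of X, and one recovered
#' direction suffices to reproduce X exactly.
#'
#' @return list with \code{X}, \code{W0}, \code{H0} (all 2 x 2).
#' @export
fixture2x2 <- function() {
  list(X = matrix(c(3.0, 0.84, 0.385, 0.8087), 2, 2),
       W0 = matrix(c(1.5012, 0.2252, 0.0000, 1.2493), 2, 2),
       H0 = matrix(c(1.4655, 0.0000, 0.6395, 0.9605), 2, 2))
}

#' Match estimated components to ground truth
#'
#' Finds the one-to-one assignment between the columns of \code{Wtrue} and
#' \code{West} maximizing the summed Pearson correlation of matched
#' columns (exact Hungarian assignment for up to 64 components). A
#' zero-variance column has correlation 0 with everything by convention.
#'
#' @param Wtrue,West matrices with components as columns (column counts
#'   may differ; the smaller count is matched).
#' @return list with \code{matching} (data.frame: \code{true}, \code{est},
#'   \code{correlation}) and \code{meanCorrelation}.
#' @export
matchComponents <- function(Wtrue, West) {
  Wtrue <- .asDenseMatrix(Wtrue)
  West <- .asDenseMatrix(West)
  if (nrow(Wtrue) != nrow(West))
    stop("component vectors must have equal length", call. = FALSE)
  r1 <- ncol(Wtrue); r2 <- ncol(West)
  if (max(r1, r2) > 64L)
    stop("exact assignment supported for up to 64 components",
         call. = FALSE)
  C <- matrix(0, r1, r2)
  sd1 <- apply(Wtrue, 2, stats::sd)
  sd2 <- apply(West, 2, stats::sd)
  okPair <- outer(sd1 > 0, sd2 > 0, "&")
  if (any(okPair)) {
    full <- suppressWarnings(stats::cor(Wtrue, West))
    C[okPair] <- full[okPair]
  }
  nsq <- max(r1, r2)
  cost <- matrix(2, nsq, nsq)                # pad: worst cost (corr = -1)
  cost[seq_len(r1), seq_len(r2)] <- 1 - C
  assign <- .hungarian(cost)
  keep <- which(seq_len(nsq) <= r1 & assign <= r2)
  matching <- data.frame(true = keep, est = assign[keep],
                         correlation = C[cbind(keep, assign[keep])])
  matching <- matching[order(matching$true), , drop = FALSE]
  list(matching = matching,
       meanCorrelation = mean(matching$correlation))
}

# O(n^3) Hungarian algorithm (potentials + augmenting paths) for a square
# cost matrix; returns the column assigned to each row.
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (j == 0L) u[i + 1L] <- u[i + 1L] + delta
          else {
            u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
            v[j + 1L] <- v[j + 1L] - delta
          }
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}
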