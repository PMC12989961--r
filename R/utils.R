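# Internal validation helpers and small numeric utilities.

.asDenseMatrix <- function(x, arg = deparse(substitute(x))) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

.checkFinite <- function(x, arg = "X") {
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite entries", arg), call. = FALSE)
  invisible(x)
}

.checkNonnegative <- function(x, arg = "X") {
  if (any(x < 0))
    stop(sprintf("'%s' must be elementwise nonnegative", arg), call. = FALSE)
  invisible(x)
}

.checkShapes <- function(X, W, H) {
  if (nrow(W) != nrow(X) || ncol(H) != ncol(X) || ncol(W) != nrow(H))
    stop("incompatible shapes: X is ", nrow(X), "x", ncol(X),
         ", W is ", nrow(W), "x", ncol(W),
         ", H is ", nrow(H), "x", ncol(H), call. = FALSE)
  invisible(NULL)
}

.frob2 <- function(x) sum(x * x)

# Half-away-from-zero rounding (base round() rounds half to even).
.roundHalfUp <- function(x) floor(x + 0.5)

.newFit <- function(W, H, algorithm = "none", converged = FALSE,
                    iterations = 0L,
                    trace = data.frame(iteration = integer(),
                                       objective = numeric()),
                    metadata = list()) {
  new("NMFFit", W = W, H = H, algorithm = algorithm,
      converged = converged, iterations = as.integer(iterations),
      objectiveTrace = trace, metadata = metadata)
}
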