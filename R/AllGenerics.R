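#' Accessors for factorization objects
#'
#' \code{basisMatrix} returns the loading matrix W (components as columns),
#' \code{coefMatrix} the coefficient matrix H (components as rows),
#' \code{nmfRank} the number of components, and \code{objectiveTrace} the
#' recorded (iteration, objective) pairs.
#'
#' @param x an [NMFFit-class] (or, for \code{nmfRank}, a
#'   [TruncatedSVD-class]).
#' @return \code{basisMatrix}/\code{coefMatrix}: a numeric matrix;
#'   \code{nmfRank}: an integer; \code{objectiveTrace}: a data.frame.
#' @examples
#' fit <- nndsvdInit(fixture2x2()$X, r = 2)
#' basisMatrix(fit)
#' nmfRank(fit)
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname basisMatrix
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))

#' @rdname basisMatrix
#' @export
setGeneric("nmfRank", function(x) standardGeneric("nmfRank"))

#' @rdname basisMatrix
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @export
#' @rdname basisMatrix
setMethod("basisMatrix", "NMFFit", function(x) x@W)

#' @export
#' @rdname basisMatrix
setMethod("coefMatrix", "NMFFit", function(x) x@H)

#' @export
#' @rdname basisMatrix
setMethod("nmfRank", "NMFFit", function(x) ncol(x@W))

#' @export
#' @rdname basisMatrix
setMethod("nmfRank", "TruncatedSVD", function(x) x@rank)

#' @export
#' @rdname basisMatrix
setMethod("objectiveTrace", "NMFFit", function(x) x@objectiveTrace)

#' @describeIn basisMatrix the reconstruction \code{W \%*\% H} of an NMFFit.
#' @param object an [NMFFit-class].
#' @param ... ignored.
#' @export
setMethod("fitted", "NMFFit", function(object, ...) object@W %*% object@H)
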