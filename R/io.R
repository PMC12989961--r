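#' Read a dense nonnegative matrix
#'
#' Supports delimited text (comma, tab or whitespace separated, sniffed
#' from the first data line) and Matrix Market files (both \code{array}
#' and \code{coordinate} variants). Entries must be finite; negative
#' entries below \code{-1e-12} raise a validation error, tiny negatives
#' are clipped to zero with a warning.
#'
#' @param path file path.
#' @param format \code{"auto"} (by content/extension), \code{"delimited"}
#'   or \code{"matrix-market"}.
#' @return numeric matrix.
#' @export
readMatrix <- function(path, format = c("auto", "delimited",
                                        "matrix-market")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^%%MatrixMarket", first) ||
                  grepl("\\.mtx$", path, ignore.case = TRUE))
      "matrix-market" else "delimited"
  }
  X <- if (format == "matrix-market") .readMM(path) else .readDelim(path)
  if (!all(is.finite(X)))
    stop("matrix in ", path, " contains non-finite entries", call. = FALSE)
  neg <- X < 0
  if (any(X < -1e-12)) {
    worst <- arrayInd(which.min(X), dim(X))
    stop("matrix contains negative entries (e.g. ", format(min(X)),
         " at [", worst[1], ",", worst[2], "]); NMF requires nonnegative ",
         "input", call. = FALSE)
  }
  if (any(neg)) {
    warning(sum(neg), " tiny negative entr",
            if (sum(neg) == 1) "y" else "ies",
            " (>= -1e-12) clipped to zero", call. = FALSE)
    X[neg] <- 0
  }
  X
}

.readDelim <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("no data in ", path, call. = FALSE)
  sep <- if (grepl(",", lines[1])) "," else if (grepl("\t", lines[1]))
    "\t" else ""
  rows <- lapply(seq_along(lines), function(i) {
    parts <- if (sep == "") strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
             else strsplit(lines[i], sep, fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals))
      stop("could not parse line ", i, " of ", path, ": '",
           substr(lines[i], 1, 60), "'", call. = FALSE)
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop("ragged rows in ", path, " (", paste(unique(ncols),
         collapse = "/"), " fields)", call. = FALSE)
  do.call(rbind, rows)
}

.readMM <- function(path) {
  header <- tolower(readLines(path, n = 1L))
  if (grepl("\\barray\\b", header)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
    dims <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
    vals <- as.numeric(unlist(strsplit(trimws(lines[-1]),
                                       "[[:space:]]+")))
    if (length(vals) != prod(dims[1:2]))
      stop("Matrix Market array file ", path, " has ", length(vals),
           " values but declares ", dims[1], "x", dims[2], call. = FALSE)
    matrix(vals, dims[1], dims[2])   # column-major per the format
  } else {
    as.matrix(Matrix::readMM(path))
  }
}

#' Write a dense matrix
#'
#' @param X numeric matrix.
#' @param path output path.
#' @param format \code{"delimited"} (tab-separated, 17 significant
#'   digits), \code{"matrix-market"} (coordinate) or
#'   \code{"matrix-market-array"}.
#' @return invisibly, \code{path}.
#' @export
writeMatrix <- function(X, path,
                        format = c("delimited", "matrix-market",
                                   "matrix-market-array")) {
  format <- match.arg(format)
  X <- .asDenseMatrix(X)
  if (format == "delimited") {
    lines <- apply(X, 1, function(row)
      paste(sprintf("%.17g", row), collapse = "\t"))
    writeLines(lines, path)
  } else if (format == "matrix-market") {
    Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("%%MatrixMarket matrix array real general", con)
    writeLines(paste(nrow(X), ncol(X)), con)
    writeLines(sprintf("%.17g", as.vector(X)), con)
  }
  invisible(path)
}

#' Write a factorization to paired delimited files
#'
#' Writes \code{<prefix>_W.tsv}, \code{<prefix>_H.tsv} (17 significant
#' digits, which round-trips doubles exactly) and
#' \code{<prefix>_meta.yaml} holding rank, algorithm, convergence flag,
#' iteration count and any metadata.
#'
#' @param fit an [NMFFit-class].
#' @param prefix output path prefix.
#' @return invisibly, a named character vector of the files written.
#' @export
writeFactorization <- function(fit, prefix) {
  stopifnot(is(fit, "NMFFit"))
  paths <- c(W = paste0(prefix, "_W.tsv"),
             H = paste0(prefix, "_H.tsv"),
             meta = paste0(prefix, "_meta.yaml"))
  writeMatrix(fit@W, paths[["W"]])
  writeMatrix(fit@H, paths[["H"]])
  meta <- list(rank = nmfRank(fit), algorithm = fit@algorithm,
               converged = fit@converged, iterations = fit@iterations,
               metadata = .yamlSafe(fit@metadata))
  yaml::write_yaml(meta, paths[["meta"]])
  invisible(paths)
}

.yamlSafe <- function(x) {
  if (is.list(x)) return(lapply(x, .yamlSafe))
  if (is.data.frame(x)) return(as.list(x))
  if (is.numeric(x)) {
    x[is.infinite(x)] <- .Machine$double.xmax
    return(unname(x))
  }
  x
}

#' Read a factorization written by [writeFactorization()]
#'
#' @param prefix the path prefix used when writing.
#' @return an [NMFFit-class].
#' @export
readFactorization <- function(prefix) {
  W <- readMatrix(paste0(prefix, "_W.tsv"))
  H <- readMatrix(paste0(prefix, "_H.tsv"))
  metaPath <- paste0(prefix, "_meta.yaml")
  meta <- if (file.exists(metaPath)) yaml::read_yaml(metaPath) else list()
  .newFit(W, H,
          algorithm = meta$algorithm %||% "unknown",
          converged = isTRUE(meta$converged),
          iterations = meta$iterations %||% 0L,
          metadata = meta$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
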