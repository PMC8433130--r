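## Delimited-text I/O for spectral datasets.
## On-disk layout: one header row ("label"[, "group"], then the wavenumber
## grid), one row per spectrum. Numbers are written with 17 significant
## digits so a read -> write -> read cycle is an exact fixed point.

delimFor <- function(format) {
  format <- match.arg(format, c("csv", "tsv"))
  if (format == "csv") "," else "\t"
}

#' Read a spectral dataset from delimited text
#'
#' The first row is the header: a \code{label} column, an optional
#' \code{group} column, then the wavenumber grid in cm^-1 (strictly
#' increasing, no duplicates). Every following row is one spectrum.
#'
#' @param path file path.
#' @param format "csv" or "tsv".
#' @return a validated \linkS4class{SpectraSet}; row order preserved.
#' @export
readSpectra <- function(path, format = c("csv", "tsv")) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- delimFor(format)
  raw <- tryCatch(
    read.csv(path, sep = sep, check.names = FALSE, colClasses = "character"),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e)))
  if (nrow(raw) < 1L || ncol(raw) < 3L)
    stop("format error: need a label column, >= 2 wavenumbers and >= 1 row")
  header <- colnames(raw)
  if (header[1L] != "label")
    stop("format error: first column must be named 'label'")
  hasGroup <- length(header) > 1L && header[2L] == "group"
  first <- if (hasGroup) 3L else 2L
  grid <- suppressWarnings(as.numeric(header[first:length(header)]))
  if (anyNA(grid))
    stop("format error: non-numeric wavenumber in header")
  if (anyDuplicated(grid))
    stop("format error: duplicate wavenumbers in header")
  if (any(diff(grid) <= 0))
    stop("format error: wavenumber grid must be strictly increasing")
  xc <- as.matrix(raw[, first:length(header), drop = FALSE])
  x <- suppressWarnings(matrix(as.numeric(xc), nrow = nrow(xc)))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error: non-numeric intensity at row %d, column %d",
                 bad[1L], bad[2L] + first - 1L))
  }
  SpectraSet(x, grid, labels = raw$label,
             groups = if (hasGroup) raw$group else NULL)
}

#' Write a spectral dataset to delimited text
#'
#' Inverse of \code{\link{readSpectra}}: numbers carry 17 significant
#' digits, so reading the file back reproduces the grid and intensities
#' bit-identically. The attached background (if any) is not written; store
#' it as its own single-spectrum file.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param path output file path.
#' @param format "csv" or "tsv".
#' @return invisibly, \code{path}.
#' @export
writeSpectra <- function(x, path, format = c("csv", "tsv")) {
  stopifnot(is(x, "SpectraSet"))
  sep <- delimFor(format)
  grid <- wavenumbers(x)
  groups <- spectraGroups(x)
  num <- function(v) sprintf("%.17g", v)
  header <- c("label", if (!is.null(groups)) "group", num(grid))
  m <- intensityMatrix(x)
  body <- cbind(spectraLabels(x),
                if (!is.null(groups)) groups,
                matrix(num(m), nrow = nrow(m)))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  writeLines(apply(body, 1L, paste, collapse = sep), con)
  invisible(path)
}

#' Crop a dataset to a wavenumber range
#'
#' Keeps the columns whose wavenumber lies in the closed interval
#' [\code{lo}, \code{hi}]. The default 400-1800 cm^-1 window is the
#' fingerprint region used for cell spectra. Idempotent; never reorders.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param lo,hi interval bounds in cm^-1, \code{lo < hi}.
#' @return the cropped \linkS4class{SpectraSet}.
#' @export
cropRange <- function(x, lo = 400, hi = 1800) {
  stopifnot(is(x, "SpectraSet"))
  if (!(lo < hi)) stop("lo must be < hi")
  w <- wavenumbers(x)
  keep <- which(w >= lo & w <= hi)
  if (length(keep) < 2L)
    stop("range error: fewer than 2 grid points in [", lo, ", ", hi, "]")
  out <- x[keep, ]
  bg <- background(x)
  if (!is.null(bg)) {
    md <- S4Vectors::metadata(out)
    md$background <- RamanSpectrum(bg@wavenumbers[keep],
                                   bg@intensities[keep], bg@meta)
    S4Vectors::metadata(out) <- md
  }
  out
}
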