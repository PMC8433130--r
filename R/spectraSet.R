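#' Construct a RamanSpectrum
#'
#' @param wavenumbers strictly increasing Raman shifts (cm^-1), length >= 2.
#' @param intensities finite intensities (a.u.), same length.
#' @param meta optional list of provenance fields (source, well, label).
#' @return a \linkS4class{RamanSpectrum}.
#' @examples
#' rs <- RamanSpectrum(c(400, 402, 404), c(1.2, 3.4, 2.1))
#' @export
RamanSpectrum <- function(wavenumbers, intensities, meta = list()) {
  new("RamanSpectrum", wavenumbers = as.numeric(wavenumbers),
      intensities = as.numeric(intensities), meta = meta)
}

#' Construct a SpectraSet
#'
#' @param intensities numeric matrix, one spectrum per row, one wavenumber
#'   per column (n x p).
#' @param wavenumbers shared grid, strictly increasing, length p (cm^-1).
#' @param labels class label per spectrum (length n).
#' @param groups optional blind-group tag per spectrum.
#' @param background optional \linkS4class{RamanSpectrum} on the same grid,
#'   or a numeric vector of length p.
#' @return a \linkS4class{SpectraSet}.
#' @examples
#' x <- SpectraSet(matrix(1:6, 2), c(400, 410, 420), labels = c("A", "B"))
#' nSpectra(x)
#' @export
SpectraSet <- function(intensities, wavenumbers, labels,
                       groups = NULL, background = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (ncol(intensities) != length(wavenumbers))
    stop("intensities must have one column per wavenumber")
  if (nrow(intensities) != length(labels))
    stop("one label per spectrum required")
  cd <- S4Vectors::DataFrame(label = as.character(labels))
  if (!is.null(groups)) cd$group <- as.character(groups)
  if (!is.null(background) && !is(background, "RamanSpectrum"))
    background <- RamanSpectrum(wavenumbers, background)
  md <- if (is.null(background)) list() else list(background = background)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(intensities)),
    rowData = S4Vectors::DataFrame(wavenumber = wavenumbers),
    colData = cd, metadata = md)
  new("SpectraSet", se)
}

#' Wavenumber grid of a dataset
#'
#' @param x a \linkS4class{SpectraSet} or \linkS4class{RamanSpectrum}.
#' @return numeric vector of Raman shifts (cm^-1).
#' @export
setMethod("wavenumbers", "SpectraSet", function(x)
  as.numeric(SummarizedExperiment::rowData(x)$wavenumber))

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "RamanSpectrum", function(x) x@wavenumbers)

#' Intensity matrix, spectra in rows
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return numeric matrix n x p (spectra x wavenumbers).
#' @export
setMethod("intensityMatrix", "SpectraSet", function(x)
  t(SummarizedExperiment::assay(x, "intensity")))

#' Per-spectrum class labels and group tags
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return character vector (groups: NULL when absent).
#' @export
setMethod("spectraLabels", "SpectraSet", function(x)
  as.character(SummarizedExperiment::colData(x)$label))

#' @rdname spectraLabels
#' @export
setMethod("spectraGroups", "SpectraSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("group" %in% colnames(cd)) as.character(cd$group) else NULL
})

#' Substrate background spectrum
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return the \linkS4class{RamanSpectrum} recorded from the bare substrate,
#'   or NULL when none is attached.
#' @export
setMethod("background", "SpectraSet", function(x)
  S4Vectors::metadata(x)$background)

#' Number of spectra / wavenumbers
#'
#' @param x a \linkS4class{SpectraSet}.
#' @export
nSpectra <- function(x) ncol(x)

#' @rdname nSpectra
#' @export
nWavenumbers <- function(x) nrow(x)

#' Subset a SpectraSet to the spectra of one class
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param label class label to keep.
#' @return a \linkS4class{SpectraSet} with only the matching spectra.
#' @export
subsetByLabel <- function(x, label) {
  keep <- spectraLabels(x) == label
  if (!any(keep)) stop("no spectra labeled '", label, "'")
  x[, keep]
}

setMethod("show", "SpectraSet", function(object) {
  w <- wavenumbers(object)
  labs <- spectraLabels(object)
  cat(sprintf(
    "SpectraSet: %d spectra x %d wavenumbers (%.1f-%.1f cm^-1)\n",
    ncol(object), nrow(object), min(w), max(w)))
  tab <- table(labs)
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab),
                        collapse = ", "), "\n")
  cat("background:",
      if (is.null(background(object))) "none" else "attached", "\n")
})

setMethod("show", "RamanSpectrum", function(object) {
  cat(sprintf("RamanSpectrum: %d points, %.1f-%.1f cm^-1\n",
              length(object@wavenumbers), min(object@wavenumbers),
              max(object@wavenumbers)))
})
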