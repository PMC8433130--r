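## Spectral cleaning and peak-window feature extraction:
## background subtraction, saturation-outlier flagging/removal, and the
## 3-shift window maximum over the selected Raman-shift panel.

#' Subtract the substrate background from every spectrum
#'
#' The spectrum recorded from the bare SERS substrate is subtracted from
#' each row; negative residuals are preserved (no clipping). The dataset's
#' stored background is cleared afterwards.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param bg a \linkS4class{RamanSpectrum} on the same grid, or a numeric
#'   vector of length p; defaults to \code{background(x)}.
#' @return the background-subtracted \linkS4class{SpectraSet}.
#' @export
subtractBackground <- function(x, bg = background(x)) {
  stopifnot(is(x, "SpectraSet"))
  if (is.null(bg)) stop("no background attached and none supplied")
  w <- wavenumbers(x)
  if (is(bg, "RamanSpectrum")) {
    if (length(bg@wavenumbers) != length(w) || any(bg@wavenumbers != w))
      stop("alignment error: background grid does not match dataset grid")
    bgv <- bg@intensities
  } else {
    bgv <- as.numeric(bg)
    if (length(bgv) != length(w))
      stop("alignment error: background length does not match grid")
  }
  a <- SummarizedExperiment::assay(x, "intensity") - bgv
  out <- SpectraSet(t(a), w, labels = spectraLabels(x),
                    groups = spectraGroups(x))
  out
}

#' Flag saturation outliers
#'
#' A spectrum is an outlier when its maximum intensity is strictly over the
#' threshold (default 2000 a.u.), the saturation rule used for SERS spectra
#' of cells.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param threshold a.u., > 0.
#' @return logical vector, one flag per spectrum.
#' @export
flagOutliers <- function(x, threshold = 2000) {
  stopifnot(is(x, "SpectraSet"), threshold > 0)
  m <- SummarizedExperiment::assay(x, "intensity")
  unname(apply(m, 2L, max) > threshold)
}

#' Drop flagged spectra
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param mask logical vector from \code{\link{flagOutliers}}.
#' @return the surviving spectra, original order preserved.
#' @export
dropOutliers <- function(x, mask = flagOutliers(x)) {
  stopifnot(is(x, "SpectraSet"), length(mask) == ncol(x))
  if (all(mask)) stop("all spectra flagged as outliers; nothing remains")
  x[, !mask]
}

#' Construct a peak panel
#'
#' @param centers strictly increasing Raman shifts (cm^-1); the default is
#'   the 16-shift panel selected for the cell lines.
#' @param windowSteps grid steps inspected on each side of the nominal
#'   shift; 1 (default) gives the 3-shift window.
#' @return a \linkS4class{PeakPanel}.
#' @export
peakPanel <- function(centers = panelCentersTable1, windowSteps = 1L) {
  new("PeakPanel", centers = as.numeric(centers),
      windowSteps = as.integer(windowSteps))
}

#' @rdname panelCenters
#' @param x a \linkS4class{PeakPanel} or \linkS4class{FeatureTable}.
#' @return numeric vector of Raman shifts.
#' @export
setMethod("panelCenters", "PeakPanel", function(x) x@centers)

#' Default peak panel shipped with the package
#'
#' Reads the 16 selected Raman shifts from inst/extdata/default_panel.csv.
#'
#' @param windowSteps window half-width in grid steps.
#' @return a \linkS4class{PeakPanel}.
#' @export
defaultPanel <- function(windowSteps = 1L) {
  f <- system.file("extdata", "default_panel.csv", package = "sersNGK")
  centers <- read.csv(f)$center
  peakPanel(centers, windowSteps)
}

#' Peak-window maximum intensity
#'
#' Finds the grid point nearest the nominal shift (ties to the lower
#' wavenumber) and returns the maximum intensity over that point and
#' \code{windowSteps} neighbours on each side (window truncated at the grid
#' edges). With \code{windowSteps = 1} this is the 3-shift maximum that
#' absorbs the 3-5 cm^-1 peak drift of SERS measurements.
#'
#' @param spectrum a \linkS4class{RamanSpectrum}, or a numeric intensity
#'   vector with \code{grid} supplied.
#' @param center nominal Raman shift (cm^-1), inside the grid span.
#' @param windowSteps grid steps on each side, >= 0.
#' @param grid wavenumber vector when \code{spectrum} is plain numeric.
#' @return the window maximum (a.u.).
#' @export
extractPeakIntensity <- function(spectrum, center, windowSteps = 1L,
                                 grid = NULL) {
  if (is(spectrum, "RamanSpectrum")) {
    grid <- spectrum@wavenumbers
    intens <- spectrum@intensities
  } else {
    intens <- as.numeric(spectrum)
    if (is.null(grid)) stop("grid required for a plain intensity vector")
  }
  if (center < grid[1L] || center > grid[length(grid)])
    stop("range error: center ", center, " outside the grid span")
  j <- which.min(abs(grid - center))   # ties resolve to the lower index
  win <- max(1L, j - windowSteps):min(length(grid), j + windowSteps)
  max(intens[win])
}

#' Build the peak-intensity feature table
#'
#' Applies the peak-window maximum at every panel center to every spectrum.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param panel a \linkS4class{PeakPanel}.
#' @return a \linkS4class{FeatureTable} (rows = spectra, columns = panel
#'   centers, labels and group tags carried through).
#' @export
buildFeatureTable <- function(x, panel = defaultPanel()) {
  stopifnot(is(x, "SpectraSet"), is(panel, "PeakPanel"))
  grid <- wavenumbers(x)
  if (any(panel@centers < grid[1L]) ||
      any(panel@centers > grid[length(grid)]))
    stop("range error: panel center outside the grid span")
  m <- SummarizedExperiment::assay(x, "intensity")  # p x n
  ws <- panel@windowSteps
  f <- vapply(panel@centers, function(ctr) {
    j <- which.min(abs(grid - ctr))
    win <- max(1L, j - ws):min(length(grid), j + ws)
    if (length(win) == 1L) m[win, ] else apply(m[win, , drop = FALSE], 2L, max)
  }, numeric(ncol(m)))
  f <- matrix(f, nrow = ncol(m))
  colnames(f) <- sprintf("%g", panel@centers)
  groups <- spectraGroups(x)
  new("FeatureTable", features = f, labels = spectraLabels(x),
      groups = if (is.null(groups)) character() else groups,
      centers = panel@centers)
}

#' Accessors for FeatureTable
#'
#' @param x a \linkS4class{FeatureTable}.
#' @return \code{featureMatrix}: the n x |centers| matrix;
#'   \code{panelCenters}: the centers; \code{spectraLabels} /
#'   \code{spectraGroups}: per-row annotations.
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) x@features)

#' @rdname panelCenters
#' @export
setMethod("panelCenters", "FeatureTable", function(x) x@centers)

#' @rdname featureMatrix
#' @export
setMethod("spectraLabels", "FeatureTable", function(x) x@labels)

#' @rdname featureMatrix
#' @export
setMethod("spectraGroups", "FeatureTable", function(x)
  if (length(x@groups)) x@groups else NULL)

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d spectra x %d panel shifts\n",
              nrow(object@features), length(object@centers)))
})

#' Subset a FeatureTable by rows
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param i row index (logical or integer).
#' @return the row-subset \linkS4class{FeatureTable}.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  new("FeatureTable", features = x@features[i, , drop = FALSE],
      labels = x@labels[i],
      groups = if (length(x@groups)) x@groups[i] else character(),
      centers = x@centers)
})
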