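#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom Rcpp sourceCpp
#' @useDynLib sersNGK, .registration = TRUE
#' @importFrom stats plogis quantile sd t.test var optim setNames
#' @importFrom stats predict rnorm runif
#' @importFrom utils read.csv write.table combn packageVersion
NULL

#' Single Raman spectrum
#'
#' Holds one spectrum: a strictly increasing wavenumber grid (cm^-1), the
#' intensities on that grid (arbitrary units, "a.u."), and free-form
#' provenance metadata (source id, well id, optional class label).
#' Negative intensities are permitted (they arise after background
#' subtraction).
#'
#' @slot wavenumbers numeric, strictly increasing Raman shifts in cm^-1.
#' @slot intensities numeric, same length as \code{wavenumbers}, finite.
#' @slot meta list of provenance fields.
#'
#' @export
setClass("RamanSpectrum",
  representation(wavenumbers = "numeric", intensities = "numeric",
                 meta = "list"),
  prototype(meta = list())
)

setValidity("RamanSpectrum", function(object) {
  w <- object@wavenumbers
  i <- object@intensities
  if (length(w) < 2L) return("need at least 2 grid points")
  if (length(w) != length(i))
    return("wavenumbers and intensities differ in length")
  if (any(!is.finite(w))) return("non-finite wavenumbers")
  if (any(diff(w) <= 0)) return("wavenumbers must be strictly increasing")
  if (any(!is.finite(i))) return("non-finite intensities")
  TRUE
})

#' Labeled collection of SERS spectra
#'
#' A \linkS4class{SummarizedExperiment} holding spectra as columns: the assay
#' \code{"intensity"} is a p x n matrix (p wavenumbers, n spectra), the
#' wavenumber grid lives in \code{rowData(x)$wavenumber}, per-spectrum class
#' labels in \code{colData(x)$label}, and an optional blind-group tag in
#' \code{colData(x)$group}. The substrate background spectrum, when known,
#' is stored in \code{metadata(x)$background} as a
#' \linkS4class{RamanSpectrum} on the same grid.
#'
#' Use \code{\link{SpectraSet}} to construct, and the accessors
#' \code{\link{wavenumbers}}, \code{\link{intensityMatrix}},
#' \code{\link{spectraLabels}}, \code{\link{spectraGroups}},
#' \code{\link{background}}.
#'
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"wavenumber" %in% colnames(rd))
    return("rowData must carry a 'wavenumber' column")
  w <- rd$wavenumber
  if (length(w) < 2L) return("need at least 2 wavenumbers")
  if (any(!is.finite(w)) || any(diff(w) <= 0))
    return("wavenumber grid must be finite and strictly increasing")
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% colnames(cd))
    return("colData must carry a 'label' column")
  if (anyNA(cd$label)) return("labels must not be NA")
  a <- SummarizedExperiment::assay(object, "intensity")
  if (any(!is.finite(a))) return("intensities must be finite")
  bg <- S4Vectors::metadata(object)$background
  if (!is.null(bg)) {
    if (!is(bg, "RamanSpectrum")) return("background must be a RamanSpectrum")
    if (length(bg@wavenumbers) != length(w) ||
        any(abs(bg@wavenumbers - w) > 0))
      return("background grid does not match dataset grid")
  }
  TRUE
})

#' Selected Raman-shift panel
#'
#' The set of Raman shifts (cm^-1) at which peak intensities are extracted,
#' together with the window rule: \code{windowSteps} grid points on each side
#' of the nominal shift are inspected and the maximum intensity in the window
#' is taken. The default \code{windowSteps = 1} gives the 3-shift window
#' (the nominal shift and its two neighbouring wavenumbers) that guards
#' against the 3-5 cm^-1 peak-position drift seen on SERS substrates.
#'
#' @slot centers numeric, strictly increasing Raman shifts in cm^-1.
#' @slot windowSteps integer >= 0, grid steps included on each side.
#'
#' @export
setClass("PeakPanel",
  representation(centers = "numeric", windowSteps = "integer"),
  prototype(windowSteps = 1L)
)

setValidity("PeakPanel", function(object) {
  cc <- object@centers
  if (length(cc) < 1L) return("panel needs at least one center")
  if (any(!is.finite(cc)) || any(diff(cc) <= 0))
    return("centers must be finite and strictly increasing")
  if (length(object@windowSteps) != 1L || object@windowSteps < 0L)
    return("windowSteps must be a single non-negative integer")
  TRUE
})

#' Peak-intensity feature table
#'
#' Matrix of extracted peak intensities: one row per spectrum, one column per
#' panel center (ordered as the panel), plus the per-row class labels and
#' optional group tags carried through from the source dataset.
#'
#' @slot features numeric matrix, rows = spectra, columns = panel centers.
#' @slot labels character, one class label per row.
#' @slot groups character or NULL-length, optional blind-group tag per row.
#' @slot centers numeric, the panel centers the columns correspond to.
#'
#' @export
setClass("FeatureTable",
  representation(features = "matrix", labels = "character",
                 groups = "character", centers = "numeric")
)

setValidity("FeatureTable", function(object) {
  f <- object@features
  if (ncol(f) != length(object@centers))
    return("feature columns must match panel centers")
  if (nrow(f) != length(object@labels))
    return("one label per row required")
  if (length(object@groups) && length(object@groups) != nrow(f))
    return("groups, when present, must have one entry per row")
  if (any(!is.finite(f))) return("features must be finite")
  if (any(diff(object@centers) <= 0))
    return("centers must be strictly increasing")
  TRUE
})

#' Per-variable distance cube for the garrote kernel
#'
#' For each variable j, the n x n matrix D^j with entries
#' d^j_kl = -(x_jk - x_jl)^2: symmetric, zero diagonal, all entries <= 0.
#' The garrote-weighted Gaussian Gram matrix is exp(sum_j xi_j D^j).
#'
#' @slot D list of p symmetric n x n matrices.
#' @slot n integer, rows of the underlying data matrix.
#' @slot p integer, number of variables.
#'
#' @export
setClass("DistanceCube",
  representation(D = "list", n = "integer", p = "integer")
)

setValidity("DistanceCube", function(object) {
  if (length(object@D) != object@p) return("need one matrix per variable")
  for (M in object@D) {
    if (!is.matrix(M) || nrow(M) != object@n || ncol(M) != object@n)
      return("each D^j must be n x n")
    if (any(M > 0)) return("entries of D^j must be <= 0")
  }
  TRUE
})

#' Fitted nonnegative-garrote kernel-machine classifier
#'
#' Binary kernel logistic classifier with nonnegative per-variable garrote
#' weights xi inside a Gaussian kernel: Pr(y = classes[2] | x) =
#' H(K alpha) with H the inverse logit and
#' K_kl = exp(-sum_j xi_j (x_jk - x_jl)^2) on column-standardized data.
#'
#' @slot xi numeric length p, nonnegative garrote weights ((a.u.)^-2 on the
#'   standardized scale).
#' @slot alpha numeric length n, dual coefficients.
#' @slot xTrain numeric matrix n x p, standardized training data.
#' @slot center,scale numeric length p, the training standardization.
#' @slot classes character length 2; \code{classes[2]} is the "success"
#'   class whose probability the model returns.
#' @slot lambdaAlpha,lambdaXi numeric, ridge and garrote penalties.
#' @slot objective numeric, recorded objective after each outer iteration
#'   (non-increasing).
#' @slot converged logical, FALSE carries a non-convergence warning status.
#' @slot link character, the inverse-link identifier ("logit").
#'
#' @export
setClass("NGKModel",
  representation(xi = "numeric", alpha = "numeric", xTrain = "matrix",
                 center = "numeric", scale = "numeric",
                 classes = "character", lambdaAlpha = "numeric",
                 lambdaXi = "numeric", objective = "numeric",
                 converged = "logical", link = "character"),
  prototype(link = "logit", converged = TRUE)
)

setValidity("NGKModel", function(object) {
  if (length(object@alpha) != nrow(object@xTrain))
    return("alpha must have one entry per training row")
  if (length(object@xi) != ncol(object@xTrain))
    return("xi must have one entry per variable")
  if (any(object@xi < 0)) return("garrote weights must be nonnegative")
  if (any(!is.finite(object@xi)) || any(!is.finite(object@alpha)))
    return("model coefficients must be finite")
  if (length(object@classes) != 2L) return("binary classifier: two classes")
  if (object@lambdaAlpha <= 0) return("lambdaAlpha must be > 0")
  if (object@lambdaXi < 0) return("lambdaXi must be >= 0")
  TRUE
})

#' Repeated cross-validation result for one cell-line pair
#'
#' Stores the per-repetition prediction values (percent correct, one value
#' per repetition = mean over the k fold accuracies), the full fold-level
#' accuracies, and the five-number summary (min, Q25, median, Q75, max)
#' used for box plots.
#'
#' @slot pair character length 2, the two class labels compared.
#' @slot accuracies numeric, per-repetition prediction values in percent.
#' @slot foldAccuracies numeric matrix k x repeats of per-fold accuracies (%).
#' @slot summary named numeric length 5: min, q25, median, q75, max.
#' @slot k,repeats integer fold count and repetition count.
#' @slot seed integer seed the fold shuffles were derived from.
#'
#' @export
setClass("CVResult",
  representation(pair = "character", accuracies = "numeric",
                 foldAccuracies = "matrix", summary = "numeric",
                 k = "integer", repeats = "integer", seed = "integer")
)

setValidity("CVResult", function(object) {
  a <- object@accuracies
  if (any(a < 0 | a > 100)) return("accuracies must lie in [0, 100]")
  s <- object@summary
  if (length(s) != 5L) return("summary must have five numbers")
  if (any(diff(s) < -1e-9)) return("summary must be non-decreasing")
  TRUE
})

#' Blind-group assignment result
#'
#' For one blind test group: the Welch two-sample t statistic and two-sided
#' p value against each candidate reference line (computed on the pooled
#' panel intensities), and the assigned label (smallest |t|; ties broken by
#' larger p, then candidate order).
#'
#' @slot group character, the blind-group tag (e.g. "TG1").
#' @slot perCandidate data.frame with columns label, t, p, df.
#' @slot assigned character, the matched reference label.
#'
#' @export
setClass("BlindMatchResult",
  representation(group = "character", perCandidate = "data.frame",
                 assigned = "character")
)

setValidity("BlindMatchResult", function(object) {
  pc <- object@perCandidate
  if (!all(c("label", "t", "p") %in% colnames(pc)))
    return("perCandidate needs columns label, t, p")
  if (length(object@assigned) != 1L ||
      !object@assigned %in% pc$label)
    return("assigned must be exactly one of the candidates")
  TRUE
})
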