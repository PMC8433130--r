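#' @rdname wavenumbers
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname intensityMatrix
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname spectraLabels
#' @export
setGeneric("spectraLabels", function(x) standardGeneric("spectraLabels"))

#' @rdname spectraLabels
#' @export
setGeneric("spectraGroups", function(x) standardGeneric("spectraGroups"))

#' @rdname background
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' Garrote-weighted Gaussian Gram matrix
#'
#' Computes K with entries K_kl = exp(sum_j xi_j d^j_kl)
#' = exp(-sum_j xi_j (x_jk - x_jl)^2): symmetric, unit diagonal, entries in
#' (0, 1], positive semidefinite for any xi >= 0. Exponents are floored at
#' -700 before exponentiation to avoid subnormal underflow.
#'
#' @param x a \linkS4class{DistanceCube}, or the n x p data matrix itself
#'   (the matrix method computes the weighted squared distances directly,
#'   without materialising the cube; both routes agree exactly up to
#'   floating-point associativity).
#' @param xi numeric vector of p nonnegative garrote weights.
#' @return n x n numeric matrix.
#' @export
setGeneric("gramMatrix", function(x, xi) standardGeneric("gramMatrix"))

#' @rdname featureMatrix
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname panelCenters
#' @export
setGeneric("panelCenters", function(x) standardGeneric("panelCenters"))
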