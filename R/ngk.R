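## Nonnegative garrote on a kernel machine (NGK).
##
## Model: Pr(y = classes[2] | x) = H(K alpha), H = inverse logit,
## K_kl = exp(sum_j xi_j d^j_kl), d^j_kl = -(x_jk - x_jl)^2, xi_j >= 0.
##
## Objective (minimized):
##   NLL(alpha, xi) + lambdaAlpha * alpha' K alpha + lambdaXi * sum(xi)
## fitted by alternating a damped-Newton ridge kernel-logistic step in alpha
## with a box-constrained quasi-Newton (L-BFGS-B) step in xi. K and the
## xi-gradient are evaluated through BLAS-level identities rather than the
## p-long stack of n x n distance matrices, so p in the hundreds is cheap.

#' Per-variable distance cube
#'
#' D^j has entries -(x_jk - x_jl)^2: the building blocks of the
#' garrote-weighted Gaussian kernel. Intended for inspection and small
#' problems; the fitter computes the kernel without materialising the cube.
#'
#' @param x numeric matrix n x p, finite.
#' @return a \linkS4class{DistanceCube}.
#' @export
distanceCube <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("validation error: non-finite values in x")
  D <- lapply(seq_len(ncol(x)), function(j) -outer(x[, j], x[, j], `-`)^2)
  new("DistanceCube", D = D, n = nrow(x), p = ncol(x))
}

clampExp <- function(e) {
  e[e < -700] <- -700
  exp(e)
}

#' @rdname gramMatrix
#' @export
setMethod("gramMatrix", c("DistanceCube", "numeric"), function(x, xi) {
  if (length(xi) != x@p) stop("xi must have length p")
  if (any(xi < 0)) stop("constraint error: negative garrote weight")
  S <- Reduce(`+`, Map(`*`, xi, x@D), accumulate = FALSE)
  if (is.null(dim(S))) S <- matrix(0, x@n, x@n)
  clampExp(S)
})

## Fast path: K = exp(-(q 1' + 1 q' - 2 Xw Xw')), q = rowSums(Xw^2),
## Xw = X scaled by sqrt(xi) columnwise; compiled (src/ngk_core.cpp).
#' @rdname gramMatrix
#' @export
setMethod("gramMatrix", c("matrix", "numeric"), function(x, xi) {
  if (length(xi) != ncol(x)) stop("xi must have length p")
  if (any(xi < 0)) stop("constraint error: negative garrote weight")
  storage.mode(x) <- "double"
  cppGram(x, as.numeric(xi))
})

## Cross kernel between new rows and training rows; zero-weight variables
## contribute nothing, so only the active columns are passed down.
crossGram <- function(a, b, xi) {
  act <- which(xi > 0)
  storage.mode(a) <- "double"
  storage.mode(b) <- "double"
  cppCrossGram(a[, act, drop = FALSE], b[, act, drop = FALSE],
               as.numeric(xi[act]))
}

## Stable sum(log(1 + exp(eta))).
log1pexp <- function(eta) ifelse(eta > 0, eta + log1p(exp(-eta)),
                                 log1p(exp(eta)))

## Negative Bernoulli log-likelihood + ridge, given K alpha pieces.
ngkObjective <- function(K, alpha, y, lambdaAlpha, lambdaXi, xi) {
  eta <- drop(K %*% alpha)
  sum(log1pexp(eta)) - sum(y * eta) +
    lambdaAlpha * drop(crossprod(alpha, eta)) + lambdaXi * sum(xi)
}

#' Fitting control parameters
#'
#' @param lambdaAlpha ridge penalty on the dual coefficients (> 0).
#' @param lambdaXi garrote (L1, nonnegativity-constrained) penalty on the
#'   variable weights (>= 0).
#' @param tol relative objective-change stopping tolerance of the outer
#'   alternation.
#' @param maxIter maximum outer iterations.
#' @param xiMaxit L-BFGS-B iteration cap inside each xi step.
#' @param standardize z-score the columns on the training data before
#'   computing distances.
#' @return list of class "ngkControl".
#' @export
ngkControl <- function(lambdaAlpha = 0.1, lambdaXi = 1, tol = 1e-5,
                       maxIter = 100L, xiMaxit = 15L, standardize = TRUE) {
  stopifnot(lambdaAlpha > 0, lambdaXi >= 0, tol > 0, maxIter >= 1)
  structure(list(lambdaAlpha = lambdaAlpha, lambdaXi = lambdaXi, tol = tol,
                 maxIter = as.integer(maxIter), xiMaxit = as.integer(xiMaxit),
                 standardize = isTRUE(standardize)), class = "ngkControl")
}

## Ridge kernel-logistic alpha step: damped Newton on
## sum log(1+exp(eta)) - y'eta + lambdaAlpha alpha'K alpha, eta = K alpha.
## Gradient K(p - y) + 2 lambda K alpha; Hessian K W K + 2 lambda K.
## Compiled core in src/ngk_core.cpp; halving line search guarantees descent.
alphaStep <- function(K, y, alpha, lambdaAlpha, maxit = 60L, gtol = 1e-10) {
  res <- cppAlphaNewton(K, as.numeric(y), as.numeric(alpha), lambdaAlpha,
                        as.integer(maxit), gtol)
  list(alpha = drop(res$alpha), value = res$value)
}

## xi step: box-constrained quasi-Newton on xi >= 0 with alpha fixed.
## dObj/dxi_j = sum_kl M_kl d^j_kl with M = K o ((p - y) alpha' +
## lambdaAlpha alpha alpha'), expanded through rowSums/crossprod identities.
##
## Variables with xi_j = 0 contribute nothing to the kernel, so the search
## runs on the active set only (exact, not an approximation); when
## fullCheck is TRUE a full-dimension KKT gradient check lets zero
## variables whose gradient is negative re-enter, and the step repeats.
xiStep <- function(X, y, alpha, xi, lambdaAlpha, lambdaXi, maxit = 50L,
                   fullCheck = TRUE) {
  p <- ncol(X)
  act <- which(xi > 0)
  if (length(act) == 0L) act <- seq_len(p)
  value <- NULL
  for (sweepIt in 1:4) {
    Xa <- X[, act, drop = FALSE]
    ## optim calls fn and gr at the same point: evaluate both at once and
    ## cache per parameter vector
    cache <- new.env(parent = emptyenv())
    evalAt <- function(x_) {
      if (is.null(cache$par) || !identical(cache$par, x_)) {
        cache$par <- x_
        og <- cppXiObjGrad(Xa, x_, alpha, y, lambdaAlpha, lambdaXi, sum(x_))
        cache$value <- og$value
        cache$grad <- drop(og$grad)
      }
      invisible(NULL)
    }
    fn <- function(x_) { evalAt(x_); cache$value }
    gr <- function(x_) { evalAt(x_); cache$grad }
    inner <- if (length(act) > 200L) min(maxit, 8L) else maxit
    res <- optim(xi[act], fn, gr, method = "L-BFGS-B", lower = 0,
                 upper = 1e8, control = list(maxit = inner, factr = 1e9))
    f0 <- fn(xi[act])
    cand <- xi
    cand[act] <- if (res$value <= f0) res$par else xi[act]
    value <- min(res$value, f0)
    xi <- cand
    if (!fullCheck) break
    ## KKT screen over the zero variables on the full dimension
    og <- cppXiObjGrad(X, xi, alpha, y, lambdaAlpha, lambdaXi, sum(xi))
    viol <- which(xi <= 0 & drop(og$grad) < -1e-8)
    if (length(viol) == 0L) break
    act <- sort(union(which(xi > 0), viol))
  }
  K <- gramMatrix(X[, which(xi > 0), drop = FALSE], xi[xi > 0])
  list(xi = xi, value = value, K = K)
}

#' Fit the NGK classifier
#'
#' Alternates a convex ridge kernel-logistic step in the dual coefficients
#' alpha with a nonnegativity-constrained garrote step in the per-variable
#' weights xi, until the relative change of the penalized objective falls
#' below \code{control$tol} (or \code{maxIter} outer iterations, in which
#' case the model carries \code{converged = FALSE} with a warning). The
#' recorded objective trace is non-increasing.
#'
#' Initialization: columns are z-scored on the training data,
#' xi_j = 1 / (p * pooled variance) (a unit-scale Gaussian kernel, so the
#' first alpha step is a plain kernel-logistic fit) and alpha = 0.
#'
#' @param x numeric matrix n x p of training features (spectra intensities
#'   or panel features), or a \linkS4class{SpectraSet} /
#'   \linkS4class{FeatureTable}.
#' @param y class label per row; exactly two distinct values.
#' @param control a \code{\link{ngkControl}}.
#' @return an \linkS4class{NGKModel}.
#' @export
ngkFit <- function(x, y = NULL, control = ngkControl()) {
  if (is(x, "SpectraSet")) {
    if (is.null(y)) y <- spectraLabels(x)
    x <- intensityMatrix(x)
  } else if (is(x, "FeatureTable")) {
    if (is.null(y)) y <- spectraLabels(x)
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("validation error: non-finite values in x")
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L)
    stop("label error: need exactly two classes, got ", length(classes))
  if (nrow(x) < 4L) stop("need n >= 4 training rows")
  y01 <- as.numeric(y == classes[2L])

  if (control$standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, `/`)

  p <- ncol(xs)
  pooledVar <- mean(apply(xs, 2L, var))
  if (!is.finite(pooledVar) || pooledVar <= 0) pooledVar <- 1
  xi <- rep(1 / (p * pooledVar), p)
  alpha <- rep(0, length(y01))

  K <- gramMatrix(xs, xi)
  objTrace <- ngkObjective(K, alpha, y01, control$lambdaAlpha,
                           control$lambdaXi, xi)
  converged <- FALSE
  forceFull <- FALSE
  for (it in seq_len(control$maxIter)) {
    a <- alphaStep(K, y01, alpha, control$lambdaAlpha)
    alpha <- a$alpha
    full <- forceFull || it <= 3L || it %% 5L == 0L
    xs_ <- xiStep(xs, y01, alpha, xi, control$lambdaAlpha,
                  control$lambdaXi, control$xiMaxit, fullCheck = full)
    xi <- xs_$xi
    K <- xs_$K
    objNew <- ngkObjective(K, alpha, y01, control$lambdaAlpha,
                           control$lambdaXi, xi)
    objPrev <- objTrace[length(objTrace)]
    objTrace <- c(objTrace, objNew)
    if (abs(objPrev - objNew) < control$tol * max(1, abs(objPrev))) {
      ## only stop on an iteration whose xi step passed the full KKT screen
      if (full) {
        converged <- TRUE
        break
      }
      forceFull <- TRUE
    } else forceFull <- FALSE
  }
  if (!converged)
    warning("NGK fit did not converge in ", control$maxIter,
            " outer iterations")
  new("NGKModel", xi = xi, alpha = alpha, xTrain = xs, center = ctr,
      scale = scl, classes = classes, lambdaAlpha = control$lambdaAlpha,
      lambdaXi = control$lambdaXi, objective = objTrace,
      converged = converged, link = "logit")
}

#' Predict classes from a fitted NGK model
#'
#' New rows are standardized with the training parameters; the cross kernel
#' K_new[i, k] = exp(-sum_j xi_j (xnew_ij - xtrain_kj)^2) feeds the logistic
#' link. A row is labeled \code{classes[2]} when its probability exceeds
#' 0.5; an exact tie goes to \code{classes[1]}.
#'
#' @param object an \linkS4class{NGKModel}.
#' @param newdata matrix m x p (or \linkS4class{SpectraSet} /
#'   \linkS4class{FeatureTable}); m = 0 returns empty output.
#' @param ... unused.
#' @return list with \code{probability} (P(classes[2])) and \code{label}.
#' @export
setMethod("predict", "NGKModel", function(object, newdata, ...) {
  if (is(newdata, "SpectraSet")) newdata <- intensityMatrix(newdata)
  if (is(newdata, "FeatureTable")) newdata <- featureMatrix(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object@xTrain))
    stop("shape error: newdata has ", ncol(newdata),
         " columns; model expects ", ncol(object@xTrain))
  if (nrow(newdata) == 0L)
    return(list(probability = numeric(0), label = character(0)))
  xs <- sweep(sweep(newdata, 2L, object@center), 2L, object@scale, `/`)
  Knew <- crossGram(xs, object@xTrain, object@xi)
  pr <- plogis(drop(Knew %*% object@alpha))
  lab <- ifelse(pr > 0.5, object@classes[2L], object@classes[1L])
  list(probability = pr, label = lab)
})

setMethod("show", "NGKModel", function(object) {
  cat(sprintf(paste0(
    "NGKModel: %s vs %s, n = %d, p = %d\n",
    "  active garrote weights (xi > 1e-8): %d; lambdaAlpha = %g, ",
    "lambdaXi = %g\n  objective %.4f -> %.4f in %d outer iterations%s\n"),
    object@classes[1L], object@classes[2L], nrow(object@xTrain),
    ncol(object@xTrain), sum(object@xi > 1e-8), object@lambdaAlpha,
    object@lambdaXi, object@objective[1L],
    object@objective[length(object@objective)],
    length(object@objective) - 1L,
    if (object@converged) "" else " (not converged)"))
})

#' Tune NGK penalties by inner cross-validation
#'
#' Grid search over (lambdaAlpha, lambdaXi) scored by stratified
#' \code{innerFolds}-fold CV accuracy. Ties prefer the larger lambdaXi
#' (more parsimonious selection), then the smaller lambdaAlpha.
#'
#' @param x,y training features and binary labels as in \code{\link{ngkFit}}.
#' @param lambdaAlphaGrid,lambdaXiGrid logarithmic grids to search.
#' @param innerFolds folds of the inner CV.
#' @param seed integer seed for the fold shuffle.
#' @param control baseline \code{\link{ngkControl}} whose penalties are
#'   overridden by each grid point.
#' @return list: \code{control} (best ngkControl), \code{table} (grid with
#'   mean CV accuracy per point).
#' @export
ngkTune <- function(x, y, lambdaAlphaGrid = c(0.01, 0.1),
                    lambdaXiGrid = c(0.1, 1, 10), innerFolds = 5L,
                    seed = 1L, control = ngkControl()) {
  if (is(x, "SpectraSet") || is(x, "FeatureTable")) {
    if (is.null(y)) y <- spectraLabels(x)
    x <- if (is(x, "FeatureTable")) featureMatrix(x) else intensityMatrix(x)
  }
  y <- as.character(y)
  grid <- expand.grid(lambdaAlpha = lambdaAlphaGrid,
                      lambdaXi = lambdaXiGrid)
  folds <- withSeed(seed, stratifiedFolds(y, innerFolds))
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    ctl <- control
    ctl$lambdaAlpha <- grid$lambdaAlpha[i]
    ctl$lambdaXi <- grid$lambdaXi[i]
    hits <- 0L
    for (f in seq_len(innerFolds)) {
      tr <- folds != f
      fit <- suppressWarnings(ngkFit(x[tr, , drop = FALSE], y[tr], ctl))
      pred <- predict(fit, x[!tr, , drop = FALSE])
      hits <- hits + sum(pred$label == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  grid$accuracy <- acc
  ord <- order(-grid$accuracy, -grid$lambdaXi, grid$lambdaAlpha)
  best <- grid[ord[1L], ]
  ctl <- control
  ctl$lambdaAlpha <- best$lambdaAlpha
  ctl$lambdaXi <- best$lambdaXi
  list(control = ctl, table = grid)
}

#' One-vs-one multiclass wrapper
#'
#' Fits one binary NGK model per unordered class pair and predicts by
#' majority vote (vote ties go to the earliest class in sorted order).
#'
#' @param x,y features and labels (>= 2 classes).
#' @param control a \code{\link{ngkControl}} shared by all pairs.
#' @return list of class "ngkOvO" with the pairwise models.
#' @export
ngkFitOvO <- function(x, y, control = ngkControl()) {
  y <- as.character(y)
  classes <- sort(unique(y))
  pairs <- combn(classes, 2L, simplify = FALSE)
  models <- lapply(pairs, function(pp) {
    keep <- y %in% pp
    ngkFit(x[keep, , drop = FALSE], y[keep], control)
  })
  structure(list(models = models, classes = classes), class = "ngkOvO")
}

#' @rdname ngkFitOvO
#' @param object an "ngkOvO" fit.
#' @param newdata feature matrix m x p.
#' @export
predictOvO <- function(object, newdata) {
  votes <- matrix(0L, nrow(as.matrix(newdata)), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (m in object$models) {
    lab <- predict(m, newdata)$label
    for (cl in m@classes) votes[, cl] <- votes[, cl] + (lab == cl)
  }
  object$classes[apply(votes, 1L, which.max)]
}
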