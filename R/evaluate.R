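## Evaluation protocols: repeated stratified 10-fold cross-validated
## pairwise prediction values with five-number summaries, and blind-group
## assignment by Welch two-sample t statistics on pooled panel intensities.

#' Five-number summary
#'
#' Minimum, 25th percentile, median, 75th percentile and maximum, with
#' linear interpolation between order statistics (quantile type 7) — the
#' box-plot statistics used to summarise prediction values.
#'
#' @param values non-empty numeric vector (percent or any unit).
#' @return named numeric vector (min, q25, median, q75, max).
#' @export
fiveNumberSummary <- function(values) {
  if (length(values) == 0L) stop("empty value list")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  c(min = min(values), q25 = q[1L], median = q[2L], q75 = q[3L],
    max = max(values))
}

#' Repeated k-fold cross-validated pairwise discrimination
#'
#' Pools the two datasets, then for each repetition draws a fresh
#' stratified k-fold split (shuffles derived from \code{seed}), fits the
#' NGK classifier on each training fold and scores the held-out fold. The
#' prediction value of a repetition is the mean of its k fold accuracies,
#' in percent; the five-number summary over repetitions feeds the box plot.
#'
#' @param a,b the two classes: \linkS4class{SpectraSet}s on the same grid,
#'   \linkS4class{FeatureTable}s on the same panel, or plain matrices with
#'   the same columns. Each input is treated as one class; its label is the
#'   unique spectra label when there is one, else "A"/"B".
#' @param k folds (default 10); every class needs >= k rows.
#' @param repeats repetitions (default 10).
#' @param seed integer seed for the fold shuffles.
#' @param control \code{\link{ngkControl}} used for every fold fit.
#' @return a \linkS4class{CVResult}.
#' @export
crossValidatePair <- function(a, b, k = 10L, repeats = 10L, seed = 1L,
                              control = ngkControl()) {
  toXY <- function(obj, fallback) {
    if (is(obj, "SpectraSet")) {
      m <- intensityMatrix(obj); l <- unique(spectraLabels(obj))
    } else if (is(obj, "FeatureTable")) {
      m <- featureMatrix(obj); l <- unique(spectraLabels(obj))
    } else {
      m <- as.matrix(obj); l <- fallback
    }
    if (nrow(m) == 0L) stop("empty dataset")
    list(x = m, label = if (length(l) == 1L) l else fallback)
  }
  A <- toXY(a, "A")
  B <- toXY(b, "B")
  if (ncol(A$x) != ncol(B$x))
    stop("the two datasets must share the same grid/feature columns")
  if (identical(A$label, B$label)) {
    A$label <- paste0(A$label, ".a")
    B$label <- paste0(B$label, ".b")
  }
  x <- rbind(A$x, B$x)
  y <- c(rep(A$label, nrow(A$x)), rep(B$label, nrow(B$x)))
  k <- as.integer(k)
  repeats <- as.integer(repeats)
  foldAcc <- matrix(NA_real_, k, repeats)
  for (r in seq_len(repeats)) {
    folds <- withSeed(deriveSeed(seed, r), stratifiedFolds(y, k))
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- suppressWarnings(
        ngkFit(x[tr, , drop = FALSE], y[tr], control))
      pred <- predict(fit, x[!tr, , drop = FALSE])
      foldAcc[f, r] <- 100 * mean(pred$label == y[!tr])
    }
  }
  accuracies <- colMeans(foldAcc)
  new("CVResult", pair = c(A$label, B$label), accuracies = accuracies,
      foldAccuracies = foldAcc, summary = fiveNumberSummary(accuracies),
      k = k, repeats = repeats, seed = as.integer(seed))
}

setMethod("show", "CVResult", function(object) {
  s <- object@summary
  cat(sprintf(paste0(
    "CVResult: %s vs %s (%d-fold CV x %d repetitions)\n",
    "  prediction value %%: min %.1f | q25 %.1f | median %.1f | ",
    "q75 %.1f | max %.1f\n"),
    object@pair[1L], object@pair[2L], object@k, object@repeats,
    s["min"], s["q25"], s["median"], s["q75"], s["max"]))
})

#' Match a blind test group to a reference cell line
#'
#' For each candidate reference line, all panel intensities of the blind
#' group (rows x centers, flattened) are pooled and compared with the
#' candidate's pooled intensities by a Welch two-sample t test (two-sided).
#' The group is assigned to the candidate with the smallest |t| — the line
#' whose panel-intensity distribution the group's resembles most closely;
#' ties break to the larger p value, then to candidate order.
#'
#' @param tg \linkS4class{FeatureTable} of the blind group.
#' @param references named list of \linkS4class{FeatureTable}s, one per
#'   candidate line, on the same panel centers.
#' @param group label recorded for the group (defaults to its group tag).
#' @return a \linkS4class{BlindMatchResult} with all per-candidate
#'   statistics.
#' @export
matchBlindGroup <- function(tg, references, group = NULL) {
  stopifnot(is(tg, "FeatureTable"), length(references) >= 1L)
  if (is.null(names(references)))
    names(references) <- vapply(references, function(r)
      unique(spectraLabels(r))[1L], "")
  if (is.null(group)) {
    g <- unique(spectraGroups(tg))
    group <- if (length(g) == 1L) g else "TG"
  }
  pooled <- as.vector(featureMatrix(tg))
  if (length(pooled) < 2L)
    stop("statistics error: fewer than 2 pooled values in the blind group")
  stats <- lapply(names(references), function(nm) {
    ref <- references[[nm]]
    if (!isTRUE(all.equal(panelCenters(ref), panelCenters(tg))))
      stop("references and blind group must share the same panel centers")
    rv <- as.vector(featureMatrix(ref))
    if (length(rv) < 2L)
      stop("statistics error: fewer than 2 pooled values in reference ", nm)
    tt <- t.test(pooled, rv)   # Welch, two-sided
    data.frame(label = nm, t = unname(tt$statistic), p = tt$p.value,
               df = unname(tt$parameter))
  })
  pc <- do.call(rbind, stats)
  ord <- order(abs(pc$t), -pc$p, seq_len(nrow(pc)))
  new("BlindMatchResult", group = group, perCandidate = pc,
      assigned = pc$label[ord[1L]])
}

setMethod("show", "BlindMatchResult", function(object) {
  cat(sprintf("BlindMatchResult: %s recognized as %s\n", object@group,
              object@assigned))
  best <- object@perCandidate[object@perCandidate$label == object@assigned, ]
  cat(sprintf("  t = %.3f, p = %.4g; %d candidates compared\n",
              best$t, best$p, nrow(object@perCandidate)))
})
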