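## Seeded generator of synthetic SERS cell spectra. Each spectrum is
##   background + sum of Lorentzian peaks (centers jittered per spectrum)
##   + iid Gaussian channel noise,
## with a configurable fraction of spectra turned into saturation outliers
## (a narrow window scaled so the raw maximum exceeds 2000 a.u. even after
## background subtraction).

#' Peak template for the simulator
#'
#' @param center Raman shift of the peak (cm^-1).
#' @param amplitude peak height (a.u.), >= 0.
#' @param width full width at half maximum (cm^-1), > 0.
#' @param jitterSd standard deviation of the per-spectrum random shift of
#'   the center (cm^-1). The default 1.5 makes total shifts of 3-5 cm^-1
#'   (about 2-3 sd) a regular occurrence, matching the drift seen on SERS
#'   substrates.
#' @return a list of class "PeakTemplate".
#' @export
peakTemplate <- function(center, amplitude, width = 14, jitterSd = 1.5) {
  stopifnot(amplitude >= 0, width > 0, jitterSd >= 0)
  structure(list(center = center, amplitude = amplitude, width = width,
                 jitterSd = jitterSd), class = "PeakTemplate")
}

#' Cell-line spectral profile
#'
#' @param name class label.
#' @param peaks list of \code{\link{peakTemplate}}s (at least one).
#' @param baselineScale multiplier on the shared substrate background.
#' @param noiseSd additive Gaussian channel noise sd (a.u.), >= 0.
#' @return a list of class "CellLineProfile".
#' @export
cellLineProfile <- function(name, peaks, baselineScale = 1, noiseSd = 30) {
  stopifnot(length(peaks) >= 1L, noiseSd >= 0)
  structure(list(name = name, peaks = peaks, baselineScale = baselineScale,
                 noiseSd = noiseSd), class = "CellLineProfile")
}

panelCentersTable1 <- c(588, 679, 699, 757, 766, 878, 889, 1020, 1080,
                        1158, 1230, 1260, 1380, 1460, 1670, 1740)

## Peak amplitudes (a.u.) per line at the 16 panel shifts. Hand-set so that
## every pair of lines differs at well over 3 shifts, breast lines resemble
## one another more than they resemble the prostate line, and peak + background
## totals stay well below the 2000 a.u. saturation threshold.
profileAmplitudes <- function() {
  rbind(
    "MDA-MB-231"  = c(300, 420, 320, 360, 260, 200, 300, 460, 560, 260,
                      380, 300, 360, 400, 460, 240),
    "HCC-1806"    = c(280, 380, 360, 300, 240, 240, 280, 430, 520, 230,
                      420, 340, 330, 370, 430, 260),
    "MCF-10A"     = c(220, 340, 260, 420, 200, 180, 240, 380, 460, 200,
                      320, 260, 300, 340, 520, 180),
    "LNCaP-C4-2"  = c(160, 260, 200, 520, 320, 300, 180, 300, 380, 320,
                      260, 420, 240, 280, 600, 320))
}

#' Default cell-line profiles
#'
#' Four profiles named after the study's cell lines (two triple-negative
#' breast cancer lines, one normal breast epithelial line, one prostate
#' cancer line), all sharing the 16 selected Raman shifts but with
#' line-specific peak amplitudes; any two profiles differ at >= 3 shifts.
#'
#' @param noiseSd channel noise sd passed to every profile (a.u.).
#' @param jitterSd per-spectrum peak-position jitter sd (cm^-1).
#' @return named list of 4 \code{\link{cellLineProfile}}s.
#' @export
defaultProfiles <- function(noiseSd = 30, jitterSd = 1.5) {
  amp <- profileAmplitudes()
  profs <- lapply(rownames(amp), function(nm) {
    peaks <- lapply(seq_along(panelCentersTable1), function(i)
      peakTemplate(panelCentersTable1[i], amp[nm, i], jitterSd = jitterSd))
    cellLineProfile(nm, peaks, noiseSd = noiseSd)
  })
  names(profs) <- rownames(amp)
  profs
}

#' Simulator configuration
#'
#' @param profiles named list of \code{\link{cellLineProfile}}s.
#' @param nPerLine spectra per cell line (default 104, the study's per-line
#'   count).
#' @param gridLo,gridHi,p wavenumber grid: \code{p} evenly spaced points on
#'   [gridLo, gridHi] cm^-1 (defaults 400, 1800, 842).
#' @param outlierFraction fraction of spectra turned into saturation
#'   outliers (> 2000 a.u.); exactly \code{round(outlierFraction * nTotal)}
#'   spectra are affected.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return a list of class "SimConfig".
#' @export
simConfig <- function(profiles = defaultProfiles(), nPerLine = 104,
                      gridLo = 400, gridHi = 1800, p = 842,
                      outlierFraction = 0, seed = 1) {
  stopifnot(nPerLine >= 2, p >= 2,
            outlierFraction >= 0, outlierFraction < 1)
  structure(list(profiles = profiles, nPerLine = nPerLine, gridLo = gridLo,
                 gridHi = gridHi, p = p,
                 outlierFraction = outlierFraction,
                 seed = as.integer(seed)), class = "SimConfig")
}

## Smooth positive substrate curve: a few broad Gaussians plus an offset.
substrateBackground <- function(w) {
  350 * exp(-((w - 950) / 420)^2) +
    180 * exp(-((w - 1600) / 260)^2) +
    120 * exp(-((w - 480) / 180)^2) + 60
}

lorentzian <- function(w, center, amplitude, fwhm) {
  hw <- fwhm / 2
  amplitude / (1 + ((w - center) / hw)^2)
}

## One line's spectra on grid w: n x p matrix of background*scale + peaks
## (jittered centers) + noise. Draw order: per spectrum, all center jitters,
## then the noise vector.
simulateLine <- function(profile, n, w, bg) {
  p <- length(w)
  out <- matrix(0, n, p)
  base <- profile$baselineScale * bg
  for (i in seq_len(n)) {
    s <- base
    for (pk in profile$peaks) {
      ctr <- pk$center + if (pk$jitterSd > 0) rnorm(1L, 0, pk$jitterSd) else 0
      s <- s + lorentzian(w, ctr, pk$amplitude, pk$width)
    }
    out[i, ] <- s + if (profile$noiseSd > 0) rnorm(p, 0, profile$noiseSd) else 0
  }
  out
}

## Inject saturation bursts: scale a ~9-point window around a random panel
## peak of each chosen spectrum so its raw maximum lands in [2600, 3200].
injectOutliers <- function(x, w, nOut) {
  if (nOut < 1L) return(x)
  rows <- sample(nrow(x), nOut)
  for (r in rows) {
    ctr <- sample(panelCentersTable1, 1L)
    j <- which.min(abs(w - ctr))
    win <- max(1L, j - 4L):min(length(w), j + 4L)
    target <- runif(1L, 2600, 3200)
    fac <- target / max(x[r, win])
    x[r, win] <- x[r, win] * fac
  }
  x
}

#' Simulate a labeled SERS dataset
#'
#' Draws \code{nPerLine} spectra per profile on the shared grid; each
#' spectrum is the smooth substrate background plus the profile's Lorentzian
#' peaks (centers jittered Normal(0, jitterSd) per spectrum) plus iid
#' Gaussian channel noise. Exactly \code{round(outlierFraction * nTotal)}
#' spectra receive a multiplicative saturation burst pushing their raw
#' maximum above 2000 a.u. The noiseless substrate background is attached
#' as \code{background(x)}.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \linkS4class{SpectraSet}; identical seed, identical output.
#' @export
simulateSpectra <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(config$seed, {
    w <- seq(config$gridLo, config$gridHi, length.out = config$p)
    bg <- substrateBackground(w)
    mats <- lapply(config$profiles, simulateLine,
                   n = config$nPerLine, w = w, bg = bg)
    x <- do.call(rbind, mats)
    labels <- rep(vapply(config$profiles, `[[`, "", "name"),
                  each = config$nPerLine)
    nOut <- round(config$outlierFraction * nrow(x))
    x <- injectOutliers(x, w, nOut)
    SpectraSet(x, w, labels = labels, background = bg)
  })
}

#' Simulate blind test groups
#'
#' Draws one group of spectra per entry of \code{groupSizes}, each from a
#' distinct profile chosen by a hidden random permutation. The returned
#' dataset carries only the anonymous tags "TG1", "TG2", ... as labels; the
#' true line of each group is returned separately so tests can score the
#' matcher without leaking it to the matching step.
#'
#' @param config a \code{\link{simConfig}} (its seed drives both the
#'   permutation and the spectra).
#' @param groupSizes spectra per blind group; at most one group per profile.
#' @return list with elements \code{spectra} (a \linkS4class{SpectraSet}
#'   labeled TG1..TGk, groups identical to labels) and \code{truth}
#'   (named character vector TG tag -> true line).
#' @export
simulateBlindGroups <- function(config, groupSizes = rep(30L, 4L)) {
  stopifnot(inherits(config, "SimConfig"),
            length(groupSizes) <= length(config$profiles),
            all(groupSizes >= 2))
  withSeed(config$seed, {
    w <- seq(config$gridLo, config$gridHi, length.out = config$p)
    bg <- substrateBackground(w)
    perm <- sample(length(config$profiles))
    chosen <- config$profiles[perm[seq_along(groupSizes)]]
    mats <- Map(function(prof, n) simulateLine(prof, n, w, bg),
                chosen, groupSizes)
    x <- do.call(rbind, mats)
    tg <- paste0("TG", seq_along(groupSizes))
    labels <- rep(tg, groupSizes)
    nOut <- round(config$outlierFraction * nrow(x))
    x <- injectOutliers(x, w, nOut)
    truth <- setNames(vapply(chosen, `[[`, "", "name"), tg)
    list(spectra = SpectraSet(x, w, labels = labels, groups = labels,
                              background = bg),
         truth = truth)
  })
}
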