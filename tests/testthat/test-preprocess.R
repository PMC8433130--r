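test_that("background subtraction is exact row-wise arithmetic", {
  ds <- SpectraSet(rbind(c(5, 7), c(1, 2), c(0, 0)), c(400, 500),
                   labels = c("A", "B", "B"), background = c(1, 2))
  out <- subtractBackground(ds)
  expect_equal(intensityMatrix(out)[1, ], c(4, 5), ignore_attr = TRUE)
  expect_equal(intensityMatrix(out)[3, ], c(-1, -2), ignore_attr = TRUE)
  expect_null(background(out))

  # self-subtraction gives the zero matrix
  self <- SpectraSet(rbind(c(1, 2), c(1, 2)), c(400, 500),
                     labels = c("A", "B"), background = c(1, 2))
  expect_true(all(intensityMatrix(subtractBackground(self)) == 0))

  # zero background leaves data unchanged
  zero <- subtractBackground(ds, rep(0, 2))
  expect_identical(intensityMatrix(zero), intensityMatrix(ds))

  # mismatched grid is an alignment error
  expect_error(subtractBackground(ds, RamanSpectrum(c(401, 500), c(1, 2))),
               "alignment error")
})

test_that("outlier flagging uses a strict 'over threshold' rule", {
  ds <- SpectraSet(rbind(c(0, 2000), c(0, 2000.1), c(0, 0)), c(400, 500),
                   labels = c("A", "A", "B"))
  expect_equal(flagOutliers(ds), c(FALSE, TRUE, FALSE))
  expect_equal(flagOutliers(ds, threshold = 1999), c(TRUE, TRUE, FALSE))
  expect_false(any(flagOutliers(SpectraSet(matrix(0, 2, 2), c(400, 500),
                                           labels = c("A", "B")))))
})

test_that("dropOutliers removes flagged rows, keeps order, and is one-pass clean", {
  set.seed(4)
  x <- matrix(runif(10 * 3, 0, 100), 10, 3)
  x[c(2, 5, 9), 2] <- 2500
  ds <- SpectraSet(x, c(400, 500, 600), labels = rep(c("A", "B"), 5))
  mask <- flagOutliers(ds)
  expect_equal(sum(mask), 3L)
  kept <- dropOutliers(ds, mask)
  expect_equal(nSpectra(kept), 7L)
  expect_identical(intensityMatrix(kept),
                   intensityMatrix(ds)[!mask, , drop = FALSE])
  # cleaning is idempotent: nothing left to flag
  expect_false(any(flagOutliers(kept)))
  # identity when nothing is flagged
  expect_identical(intensityMatrix(dropOutliers(ds, rep(FALSE, 10))),
                   intensityMatrix(ds))
  expect_error(dropOutliers(ds, rep(TRUE, 10)), "nothing remains")
})

test_that("peak-window maximum follows the 3-shift rule with edge truncation", {
  grid <- c(1016, 1018, 1020, 1022, 1024)
  rs <- RamanSpectrum(grid, c(9, 5, 4, 6, 1))
  expect_equal(extractPeakIntensity(rs, 1020, windowSteps = 1L), 6)
  expect_equal(extractPeakIntensity(rs, 1020, windowSteps = 0L), 4)
  expect_equal(extractPeakIntensity(rs, 1020, windowSteps = 2L), 9)
  # window truncated at the grid edge
  expect_equal(extractPeakIntensity(rs, 1016, windowSteps = 1L), 9)
  expect_equal(extractPeakIntensity(rs, 1024, windowSteps = 1L), 6)
  # center equidistant between two grid points snaps to the lower one
  expect_equal(extractPeakIntensity(rs, 1019, windowSteps = 0L), 5)
  expect_error(extractPeakIntensity(rs, 1030), "range error")
})

test_that("window maximum is monotone in in-window values, blind to others", {
  set.seed(8)
  grid <- seq(400, 440, by = 2)
  v <- runif(length(grid), 0, 10)
  base <- extractPeakIntensity(v, 420, 1L, grid = grid)
  j <- which.min(abs(grid - 420))
  for (rep in 1:20) {
    v2 <- v
    inWin <- sample((j - 1):(j + 1), 1)
    v2[inWin] <- v2[inWin] + runif(1, 0, 5)
    expect_gte(extractPeakIntensity(v2, 420, 1L, grid = grid), base)
    v3 <- v
    outWin <- sample(setdiff(seq_along(grid), (j - 1):(j + 1)), 1)
    v3[outWin] <- v3[outWin] + runif(1, 0, 50)
    expect_equal(extractPeakIntensity(v3, 420, 1L, grid = grid), base)
  }
})

test_that("feature tables have panel shape and compose with outlier removal", {
  cfg <- simConfig(nPerLine = 6, seed = 3, outlierFraction = 0.25)
  ds <- subtractBackground(simulateSpectra(cfg))
  ft <- buildFeatureTable(ds)
  expect_s4_class(ft, "FeatureTable")
  expect_equal(dim(featureMatrix(ft)), c(24L, 16L))
  expect_equal(panelCenters(ft), panelCenters(defaultPanel()))

  kept <- dropOutliers(ds)
  ftKept <- buildFeatureTable(kept)
  expect_equal(nrow(featureMatrix(ftKept)), nSpectra(kept))
  expect_identical(spectraLabels(ftKept), spectraLabels(kept))

  # feature values equal the per-spectrum window extraction
  w <- wavenumbers(ds)
  i <- 5; jc <- 7
  expect_equal(featureMatrix(ft)[i, jc],
               extractPeakIntensity(intensityMatrix(ds)[i, ],
                                    panelCenters(ft)[jc], 1L, grid = w),
               ignore_attr = TRUE)

  expect_error(buildFeatureTable(ds, peakPanel(c(100, 200))), "range error")
  expect_error(peakPanel(numeric()), "at least one")
})
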