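test_that("five-number summary: exact quartiles, interpolation, invariances", {
  expect_equal(unname(fiveNumberSummary(1:5)), c(1, 2, 3, 4, 5))
  expect_equal(unname(fiveNumberSummary(c(7, 7, 7))), rep(7, 5))
  expect_equal(unname(fiveNumberSummary(c(0, 100))), c(0, 25, 50, 75, 100))
  expect_error(fiveNumberSummary(numeric()), "empty")
  # order invariance and affine equivariance
  set.seed(3)
  v <- runif(17, 0, 100)
  expect_equal(fiveNumberSummary(v), fiveNumberSummary(sample(v)))
  expect_equal(fiveNumberSummary(3 * v + 2),
               3 * fiveNumberSummary(v) + 2)
})

test_that("cross-validation runs on minimal legal input and validates k", {
  d <- separatedGaussian(n = 4, p = 3, shift = 4, seed = 5)
  a <- d$x[d$y == "a", ]
  b <- d$x[d$y == "b", ]
  res <- crossValidatePair(a, b, k = 2, repeats = 2, seed = 1)
  expect_s4_class(res, "CVResult")
  expect_length(res@accuracies, 2L)
  expect_equal(dim(res@foldAccuracies), c(2L, 2L))
  expect_true(all(res@accuracies >= 0 & res@accuracies <= 100))
  expect_equal(unname(res@summary["min"]), min(res@accuracies))
  # class smaller than k
  expect_error(crossValidatePair(a, b, k = 5, repeats = 1, seed = 1),
               "stratification error")
})

test_that("cross-validation separates what is separable and is seed-stable", {
  d <- separatedGaussian(n = 20, p = 4, inform = 2, shift = 4, seed = 8)
  a <- d$x[d$y == "a", ]
  b <- d$x[d$y == "b", ]
  r1 <- crossValidatePair(a, b, k = 4, repeats = 3, seed = 11)
  expect_gte(r1@summary[["median"]], 95)
  r2 <- crossValidatePair(a, b, k = 4, repeats = 3, seed = 11)
  expect_identical(r1@accuracies, r2@accuracies)
})

test_that("blind matching: exact zero t on copied rows, deterministic tie-break", {
  set.seed(12)
  f <- matrix(runif(8 * 4, 10, 20), 8, 4)
  mk <- function(m, lab) new("FeatureTable", features = m,
                             labels = rep(lab, nrow(m)),
                             groups = character(),
                             centers = c(500, 600, 700, 800))
  tg <- mk(f, "TG1")
  copied <- mk(f, "lineA")        # identical rows: t = 0 exactly
  other <- mk(f + 5, "lineB")
  res <- matchBlindGroup(tg, list(lineA = copied, lineB = other),
                         group = "TG1")
  expect_equal(res@assigned, "lineA")
  expect_identical(res@perCandidate$t[res@perCandidate$label == "lineA"], 0)
  # symmetric construction ties: first candidate wins
  up <- mk(f + 2, "up"); down <- mk(f - 2, "down")
  tie <- matchBlindGroup(tg, list(up = up, down = down), group = "TG1")
  tU <- tie@perCandidate$t[tie@perCandidate$label == "up"]
  tD <- tie@perCandidate$t[tie@perCandidate$label == "down"]
  expect_equal(abs(tU), abs(tD))
  expect_equal(tie@assigned, "up")
  # degenerate pooled sample
  one <- new("FeatureTable", features = matrix(1, 1, 1), labels = "TG",
             groups = character(), centers = 500)
  expect_error(matchBlindGroup(one, list(a = copied)), "same panel|statistics error")
})

test_that("blind groups simulated from a line are matched back to it", {
  cfg <- simConfig(nPerLine = 30, seed = 77)
  ds <- subtractBackground(simulateSpectra(cfg))
  panel <- peakPanel()
  refs <- lapply(names(defaultProfiles()), function(l)
    buildFeatureTable(subsetByLabel(ds, l), panel))
  names(refs) <- names(defaultProfiles())
  bg <- simulateBlindGroups(simConfig(nPerLine = 15, seed = 78),
                            groupSizes = rep(15L, 4L))
  tg <- subtractBackground(bg$spectra)
  for (tag in paste0("TG", 1:4)) {
    ft <- buildFeatureTable(tg[, spectraGroups(tg) == tag], panel)
    m <- matchBlindGroup(ft, refs, group = tag)
    expect_equal(m@assigned, unname(bg$truth[tag]))
    # the winner has the smallest |t| among all candidates
    expect_equal(m@assigned,
                 m@perCandidate$label[which.min(abs(m@perCandidate$t))])
  }
})

test_that("prediction values sit at chance under label permutation", {
  meds <- vapply(1:10, function(s) {
    set.seed(9000 + s)
    x <- matrix(rnorm(200 * 6), 200, 6)
    y <- sample(rep(c("a", "b"), each = 100))   # labels carry no signal
    cv <- crossValidatePair(x[y == "a", ], x[y == "b", ],
                            k = 5, repeats = 2, seed = s)
    cv@summary[["median"]]
  }, numeric(1))
  expect_gte(mean(meds), 42)
  expect_lte(mean(meds), 58)
})

test_that("dropping saturation outliers does not lower the median prediction value", {
  cfg <- simConfig(nPerLine = 40, outlierFraction = 0.1, seed = 55)
  ds <- subtractBackground(simulateSpectra(cfg))
  run <- function(ft)
    crossValidatePair(ft[spectraLabels(ft) == "MDA-MB-231"],
                      ft[spectraLabels(ft) == "HCC-1806"],
                      k = 4, repeats = 3, seed = 9)@summary[["median"]]
  withOutliers <- run(buildFeatureTable(ds))
  withoutOutliers <- run(buildFeatureTable(dropOutliers(ds)))
  expect_gte(withoutOutliers, withOutliers)
})

test_that("the full study report has the protocol structure and is deterministic", {
  cfg <- studyConfig(seed = 3, nPerLine = 12, outlierFraction = 0,
                     k = 3, repeats = 1, blindGroupSize = 6)
  r1 <- runFullStudy(cfg)
  expect_length(r1$cv, 6L)      # 4 choose 2 line pairs
  expect_length(r1$blind, 4L)   # TG1..TG4
  expect_true(all(vapply(r1$cv, function(z)
    length(z$predictionValues) == 1L, TRUE)))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  runFullStudy(cfg, outPath = f1)
  runFullStudy(cfg, outPath = f2)
  expect_identical(readLines(f1), readLines(f2))
})
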