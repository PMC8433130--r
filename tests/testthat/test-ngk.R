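test_that("distance cube matches the quadratic formula on hand cases", {
  dc <- distanceCube(matrix(c(3, 1), 2, 1))
  expect_equal(dc@D[[1]], rbind(c(0, -4), c(-4, 0)))
  # constant column: all zeros
  dc2 <- distanceCube(cbind(c(2, 2, 2)))
  expect_true(all(dc2@D[[1]] == 0))
  # symmetry and zero diagonal on random input
  set.seed(2)
  dc3 <- distanceCube(matrix(rnorm(12), 4, 3))
  for (D in dc3@D) {
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D <= 0))
  }
  expect_error(distanceCube(matrix(c(1, Inf), 1)), "validation error")
})

test_that("gram matrix: closed forms, both construction routes agree", {
  x <- matrix(c(0, 1), 2, 1)
  # xi = 0: all ones
  expect_equal(gramMatrix(x, 0), matrix(1, 2, 2))
  # p=1, xi=1, |x1-x2|=1: off-diagonal exp(-1)
  K <- gramMatrix(x, 1)
  expect_equal(K[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(diag(K), c(1, 1))
  # the distance-cube route and the direct matrix route agree
  set.seed(5)
  xr <- matrix(rnorm(8 * 3), 8, 3)
  xi <- runif(3)
  expect_equal(gramMatrix(distanceCube(xr), xi), gramMatrix(xr, xi),
               tolerance = 1e-12)
  expect_error(gramMatrix(xr, c(-1, 0, 0)), "constraint error")
})

test_that("gram matrix is positive semidefinite for random nonnegative weights", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    p <- sample(1:6, 1)
    K <- gramMatrix(matrix(rnorm(n * p), n, p), runif(p, 0, 2))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("kernel is invariant to column scaling compensated in xi", {
  set.seed(7)
  x <- matrix(rnorm(10 * 4), 10, 4)
  xi <- runif(4)
  cc <- c(2, 0.5, 10, 1)
  x2 <- sweep(x, 2, cc, `*`)
  expect_equal(gramMatrix(x, xi), gramMatrix(x2, xi / cc^2),
               tolerance = 1e-12)
})

test_that("alpha step matches an independent optimizer on the same objective", {
  set.seed(10)
  for (fix in 1:10) {
    n <- sample(10:40, 1)
    p <- sample(2:10, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- rep(c(0, 1), length.out = n)
    K <- gramMatrix(x, runif(p, 0, 0.5))
    la <- 10^runif(1, -2, 0)
    mine <- sersNGK:::alphaStep(K, y, rep(0, n), la)
    ref <- optim(rep(0, n), alphaObjectiveRef, K = K, y = y,
                 lambdaAlpha = la, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    expect_lt(abs(mine$value - ref$value), 1e-4)
    expect_lte(mine$value, ref$value + 1e-6)  # Newton should not be worse
  }
})

test_that("separable data are fit perfectly and reproduced by predict", {
  d <- separatedGaussian(n = 20, p = 5, inform = 1, shift = 6, seed = 3)
  fit <- ngkFit(d$x, d$y)
  expect_true(fit@converged)
  pred <- predict(fit, d$x)
  expect_equal(mean(pred$label == d$y), 1.0)
  # objective trace is monotone non-increasing
  expect_true(all(diff(fit@objective) <= 1e-9))
})

test_that("fit objective is non-increasing across varied fixtures", {
  set.seed(77)
  for (rep in 1:4) {
    n <- sample(c(12, 20), 1)
    p <- sample(c(3, 8), 1)
    x <- matrix(rnorm(2 * n * p), 2 * n, p)
    y <- rep(c("u", "v"), each = n)
    ctl <- ngkControl(lambdaXi = sample(c(0.1, 1, 5), 1))
    fit <- suppressWarnings(ngkFit(x, y, ctl))
    expect_true(all(diff(fit@objective) <= 1e-9))
  }
})

test_that("the garrote concentrates weight on the informative variable", {
  d <- separatedGaussian(n = 50, p = 3, inform = 1, shift = 3, seed = 21)
  # column 1 informative; reorder so it is column 2
  x <- d$x[, c(2, 1, 3)]
  tuned <- ngkTune(x, d$y, lambdaAlphaGrid = 0.1,
                   lambdaXiGrid = c(0.3, 1, 3), innerFolds = 3, seed = 2)
  fit <- suppressWarnings(ngkFit(x, d$y, tuned$control))
  expect_gte(fit@xi[2] / sum(fit@xi), 0.8)
})

test_that("prediction edge cases behave as documented", {
  d <- separatedGaussian(n = 10, p = 3, seed = 6)
  fit <- ngkFit(d$x, d$y)
  # zero rows: empty output
  empty <- predict(fit, d$x[0, , drop = FALSE])
  expect_length(empty$probability, 0L)
  expect_length(empty$label, 0L)
  # column mismatch: shape error
  expect_error(predict(fit, d$x[, 1:2]), "shape error")
  # an all-zero-xi model predicts a constant probability
  zfit <- fit
  zfit@xi <- rep(0, 3)
  prz <- predict(zfit, d$x)$probability
  expect_equal(length(unique(round(prz, 12))), 1L)
})

test_that("degenerate labels are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(ngkFit(x, rep("a", 10)), "label error")
  expect_error(ngkFit(x, rep(c("a", "b", "c"), length.out = 10)),
               "label error")
  expect_error(ngkFit(x[1:3, ], c("a", "b", "a")), "n >= 4")
})

test_that("adding pure-noise variables keeps the noise xi-mass small", {
  set.seed(14)
  masses <- replicate(3, {
    d <- separatedGaussian(n = 40, p = 2, inform = 2, shift = 3,
                           seed = sample.int(1e6, 1))
    xNoise <- cbind(d$x, matrix(rnorm(80 * 6), 80, 6))
    fit <- ngkFit(xNoise, d$y)
    sum(fit@xi[3:8]) / max(sum(fit@xi), 1e-12)
  })
  expect_true(all(masses <= 0.2))
})

test_that("one-vs-one wrapper recovers multiclass labels on separated data", {
  set.seed(9)
  n <- 15
  x <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2, mean = 4), n, 2),
             matrix(rnorm(n * 2, mean = c(0, 8)), n, 2))
  y <- rep(c("a", "b", "c"), each = n)
  ovo <- ngkFitOvO(x, y)
  expect_length(ovo$models, 3L)
  expect_equal(mean(predictOvO(ovo, x) == y), 1.0)
})
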