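# Small in-code fixtures shared across the suite.

# 3 spectra on a 3-point grid, two classes.
tinySet <- function() {
  SpectraSet(rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)),
             wavenumbers = c(400, 401, 402),
             labels = c("A", "A", "B"))
}

# Two well-separated classes in p dimensions with `inform` informative
# columns: class 2 is mean-shifted by `shift` pooled SDs on those columns.
separatedGaussian <- function(n = 40, p = 5, inform = 1, shift = 3,
                              seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n * p), 2 * n, p)
  x[(n + 1):(2 * n), seq_len(inform)] <-
    x[(n + 1):(2 * n), seq_len(inform)] + shift
  list(x = x, y = rep(c("a", "b"), each = n))
}

# A two-profile simulator config whose lines share one profile (null case).
nullPairConfig <- function(nPerLine = 20, seed = 1) {
  profs <- defaultProfiles()[c("MCF-10A", "MCF-10A")]
  profs[[2]]$name <- "MCF-10A-b"
  names(profs) <- c("MCF-10A", "MCF-10A-b")
  simConfig(profs, nPerLine = nPerLine, seed = seed)
}

# Reference objective for the alpha step, written independently of the
# package's Newton implementation (plain R, no shared helpers).
alphaObjectiveRef <- function(K, y, alpha, lambdaAlpha) {
  eta <- as.vector(K %*% alpha)
  sum(log(1 + exp(-abs(eta))) + pmax(eta, 0)) - sum(y * eta) +
    lambdaAlpha * sum(alpha * eta)
}
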