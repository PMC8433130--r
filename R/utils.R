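## Internal helpers: scoped RNG, derived seeds, stratified folds, logging.

## Evaluate code with the RNG seeded to `seed`, restoring the caller's RNG
## state afterwards so seeded generators do not perturb the session stream.
withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

## Deterministic sub-seed derivation, kept inside 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

## Stratified fold assignment: within each class, shuffled rows are dealt
## round-robin into k folds, so every fold holds both classes.
stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop("stratification error: class '", cl, "' has ", length(idx),
           " rows, fewer than k = ", k, "; use a smaller k")
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

logMsg <- function(..., verbose = getOption("sersNGK.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[sersNGK] ", ...)
}

## md5 of the canonical JSON serialisation of a config list.
configHash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}
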