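# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generator calls do not perturb user-level randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Truncated-normal draw on (lo, hi) by rejection with a clamping fallback.
rnorm_trunc <- function(n, mean, sd, lo = 1e-6, hi = 1 - 1e-6) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:20) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

# Reverse complement for plain character vectors (ACGTN alphabet).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
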