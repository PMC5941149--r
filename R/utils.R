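# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's state
# afterwards. All stochastic entry points funnel through this so that a
# seed fully determines output without clobbering the session RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Fixed per-generator offsets: adding a generator must never perturb the
# streams of existing ones. Offsets keep derived seeds well below 2^31.
.streamOffset <- c(assembly = 1L, contamination = 2L, codons = 3L,
                   enrichment = 4L, synteny = 5L)

subSeed <- function(seed, stream) {
  off <- .streamOffset[[stream]]
  (as.integer(seed) %% 1000000L) * 1009L + off
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a non-missing scalar", name), call. = FALSE)
  invisible(x)
}
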