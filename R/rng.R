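# Named RNG substreams: every stochastic stage draws from a seed derived from
# one root seed plus a stream label, so partial reruns (e.g. re-sampling
# covariates without re-voxelizing volumes) reproduce exactly.

# Streams used across the package; the integer offsets are arbitrary but fixed.
.stream_ids <- c(structure = 1L, noise = 2L, wmh = 3L, ages = 4L,
                 covariates = 5L, training = 6L, folds = 7L, augment = 8L,
                 stats = 9L)

#' Derive a substream seed from a root seed
#'
#' Deterministic integer mixing of a root seed with a named stream and an
#' optional index (e.g. a subject counter), kept within the 32-bit signed
#' range R requires of `set.seed()`.
#'
#' @param root_seed Integer root seed.
#' @param stream One of "structure", "noise", "wmh", "ages", "covariates",
#'   "training", "folds", "augment", "stats".
#' @param index Optional non-negative integer (subject/fold counter).
#' @return A single integer seed.
#' @export
substream_seed <- function(root_seed, stream, index = 0L) {
  sid <- .stream_ids[[match.arg(stream, names(.stream_ids))]]
  # 64-bit-safe multiplicative mixing, folded into [0, 2^31 - 1]
  h <- (as.double(root_seed) %% 2147483647) * 48271 + sid * 69621 +
    as.double(index) * 16807
  as.integer(h %% 2147483647)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
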