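# Internal helpers: seeded evaluation without disturbing the caller's RNG,
# and deterministic derivation of per-stage / per-recording seeds from one
# master seed.

withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# seed stream: master -> sub-seed for (stage, index), kept inside 32-bit range.
# Multiplier and modulus are fixed so identical masters always map to
# identical streams; stages are spaced far apart to avoid overlap.
deriveSeed <- function(master, stage, index = 0L) {
  stopifnot(is.finite(master))
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 %% m
  ((s + stage * 1e6 + index) %% (m - 1)) + 1
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
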