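# Internal helpers: RNG hygiene and deterministic seeds for cached nulls.

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit seed from a character key (so cached permutation
# nulls are reproducible across sessions and independent of user RNG).
seed_from_key <- function(key) {
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647L
  as.integer(h)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# sample() without the scalar-x surprise
sample_safe <- function(x, size) x[sample.int(length(x), size)]

# Zero-mean rectangular wave of unit fundamental-normalised peak: value
# (1 - duty) on the first `duty` fraction of the cycle (peak centred on
# phase 0), -duty elsewhere. Asymmetric duty => strong even harmonics.
rect_wave <- function(cycle_frac, duty = 0.3) {
  fr <- ((cycle_frac + duty / 2) %% 1 + 1) %% 1
  ifelse(fr < duty, 1 - duty, -duty)
}
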