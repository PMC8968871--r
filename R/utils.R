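#' @importFrom withr with_seed
NULL

# Evaluate expr under a temporary RNG state so package functions never
# disturb the caller's .Random.seed.
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derived substream seed for replicate/permutation k under a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}

.assertCount <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x))
    stop(sprintf("configuration error: '%s' must be a positive integer (got %s)",
                 name, paste(x, collapse = ",")), call. = FALSE)
  as.integer(x)
}

# which.max with an explicit NA on ties (conservative forensic convention:
# a tied top score never yields a conclusion).
.argmaxNoTies <- function(x) {
  m <- max(x)
  i <- which(x == m)
  if (length(i) != 1L) NA_integer_ else i
}
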