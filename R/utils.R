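# internal helpers shared across modules

# evaluate `code` under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  code
}

# deterministic sub-seed per event class, kept below 2^31
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7 + offset * 1301) %% 2147483629L)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * (2 * sqrt(2 * log(2)))
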