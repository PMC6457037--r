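# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed when one is given, restoring RNG state
# afterwards; with seed = NULL the global RNG stream is used as-is.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Deterministic seed chaining ("counter mode"): a small LCG step per counter,
# kept inside 2^31 - 1 so values are valid R integer seeds regardless of the
# order conditions/replicates are visited.
derive_seed <- function(master, ...) {
  m <- 2147483647
  x <- as.numeric(master) %% m
  for (k in c(...)) {
    x <- (69069 * ((x + as.numeric(k) + 1) %% m) + 12345) %% m
  }
  as.integer(x)
}

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("%s must be finite numeric", what), call. = FALSE)
  }
  invisible(x)
}

sym_part <- function(M) (M + t(M)) / 2
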