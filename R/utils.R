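# internal helpers shared across modules

# Wrap angles to (-pi, pi].
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Deterministic sub-seed derivation: fold indices into a 31-bit LCG state so a
# single master seed fixes every stage- and unit-level stream. Multiplier kept
# small enough that the products stay exact in double precision.
derive_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (idx in c(...)) {
    s <- (s * 69069 + as.numeric(idx) + 1) %% 2147483647
  }
  as.integer(s)
}

# Run `expr` under a temporary RNG state when a seed is supplied.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_hdc <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "hdclamp_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_hdc("`%s` must be a single finite number in [%s, %s]", name,
             format(lower), format(upper))
  }
  invisible(x)
}

# Polynomial rolling hash of a character scalar, returned as hex. Used for
# the run manifest's config fingerprint; stability, not cryptography, is the
# point. Exact in double precision (131 * (2^31-1) < 2^53).
config_hash <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
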