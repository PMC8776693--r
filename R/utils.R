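# Internal helpers shared across modules.

# Deterministic 31-bit stream seed derived from a base seed and an arbitrary
# string key, so per-patient / per-institution randomness is reproducible and
# independent of generation order.
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_probability <- function(p) {
  is.numeric(p) && length(p) == 1L && is.finite(p) && p >= 0 && p <= 1
}

# Population (divide-by-n) moments used throughout the feature definitions.
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))
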