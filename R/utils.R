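# Internal helpers shared across modules.

# Deterministic 31-bit hash of a string, for deriving per-entity RNG seeds
# that do not depend on evaluation order.
hash31 <- function(x) {
  v <- utf8ToInt(x)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Combine a base seed with an offset (or string) into a valid 32-bit seed.
derive_seed <- function(seed, offset = 0L) {
  if (is.character(offset)) offset <- hash31(offset)
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name),
          class = "sigrev_config_error")
  }
  if (integerish && x != floor(x)) {
    abort(sprintf("`%s` must be an integer.", name),
          class = "sigrev_config_error")
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)),
          class = "sigrev_config_error")
  }
  invisible(x)
}

`%_%` <- function(a, b) paste0(a, b)
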