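#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules: argument checking and seeded
# random-number substreams. All randomness in the package flows through
# `with_substream()` so that one project seed yields independent,
# reproducible streams for labels, features, splits, dropout, etc.

abort_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid("`%s` must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    abort_invalid("`%s` = %s is outside its allowed range", name, format(x))
  invisible(x)
}

# Deterministic 31-bit seed for a named substream of a run seed.
substream_seed <- function(seed, name) {
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 1014283
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 17) %% 2147483629)
}

# Evaluate `expr` under a seeded RNG without disturbing the caller's RNG state.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
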