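`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_("`%s` must be a single value in [0, 1]", name)
  as.numeric(x)
}

# Deterministic helper: evaluate `expr` under `seed` without touching the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
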