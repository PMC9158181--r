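# shared internal helpers

# scalar checks; stop with a typed input error
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    sq_input_error(sprintf("`%s` must be a single non-missing number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    sq_input_error(sprintf("`%s` = %g is outside its admissible range", name, x))
  invisible(x)
}

check_alpha <- function(alpha) {
  check_number(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
}

# Deterministic child-seed derivation: one master seed expands to
# per-scenario seeds by a splitmix-style counter so that grids are
# reproducible and independent of evaluation order. All arithmetic stays
# below 2^53 (exact in doubles); result is in [1, 2^31 - 2].
derive_seed <- function(master, index) {
  if (!is.numeric(master) || length(master) != 1L || is.na(master))
    sq_input_error("`seed` must be a single integer")
  m <- 2147483647  # 2^31 - 1, prime
  x <- (abs(master) %% m)
  for (k in seq_len(2L)) {
    x <- (x * 48271 + index * 30269 + k * 104729) %% m
  }
  as.integer(x %% (m - 1L) + 1L)
}

# run fn under a local RNG state seeded with `seed` (NULL = use current
# stream); the caller's RNG state is never disturbed when seed is given
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}
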