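#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
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

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x)) stop_input("'%s' must be numeric", name)
  if (length(x) < min_len)
    stop_input("'%s' must have length >= %d (got %d)", name, min_len, length(x))
  if (anyNA(x)) stop_input("'%s' contains NA", name)
  invisible(x)
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_input("'%s' must be a single non-NA number", name)
  if (strict && x <= lower) stop_input("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict && x < lower) stop_input("'%s' must be >= %g (got %g)", name, lower, x)
  invisible(x)
}
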