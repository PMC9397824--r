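#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# When `seed` is NULL the current stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation for nested simulation components.
# Keeps values in [1, 2^31 - 2] so they remain valid R integer seeds.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) s <- (s * 48271 + as.double(i) * 7919 + 1) %% 2147483647
  as.integer(s + 1)
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be a positive finite number", name), call. = FALSE)
  invisible(x)
}
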