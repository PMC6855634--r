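`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
hann_taper <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / (n - 1L)))
}

# Run code with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_num <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict_min && x <= min)
    stop(sprintf("'%s' must be > %g", name, min), call. = FALSE)
  if (!strict_min && x < min)
    stop(sprintf("'%s' must be >= %g", name, min), call. = FALSE)
  invisible(x)
}
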