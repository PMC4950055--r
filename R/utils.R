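# Internal helpers shared across modules.

# Round half away from zero (printed chart tables use this convention,
# unlike base round()'s round-half-even).
round_half_out <- function(x) trunc(x + 0.5 * sign(x))

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. A NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

assert_scalar_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_(name, " must be TRUE or FALSE")
  }
}
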