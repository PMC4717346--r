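# Internal helpers shared across modules.

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code with a private RNG stream so package internals (multi-start
# jitter, bootstrap resampling) are reproducible under a caller-supplied
# seed without clobbering the caller's RNG state.
with_private_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_ufl <- function(...) stop(..., call. = FALSE)
warn_ufl <- function(...) warning(..., call. = FALSE)
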