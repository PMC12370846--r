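# Internal helpers shared across modules.

#' Evaluate code under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not disturb the
#' caller's RNG stream. `seed = NULL` leaves the stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed; keeps values < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + k) %% 2147483647)
}

log_info <- function(...) {
  if (isTRUE(getOption("mrmediate.quiet", TRUE))) return(invisible(NULL))
  message("[mrmediate] ", sprintf(...))
}

log_warn <- function(...) warning(sprintf(...), call. = FALSE)

# 95% normal CI half-width multiplier used throughout (IVW/median/mode).
Z95 <- 1.959964

# Two-sided normal p-value from an estimate and its SE.
p_normal <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
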