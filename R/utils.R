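# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) `.Random.seed` afterwards so callers' RNG streams are
#' untouched. A `NULL` seed runs the expression against the ambient stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream of child seeds from one master seed
#'
#' Used for hierarchical (master, subject, stage) seeding so that every
#' stochastic draw in a cohort simulation is reproducible and loggable.
#' Children stay below 2^31 - 1.
#' @noRd
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("memdecay_config_error", "error")))
}

assert_band <- function(band, what) {
  if (!is.numeric(band) || length(band) != 2L || !all(is.finite(band)) ||
      band[1] >= band[2]) {
    stop_config("`", what, "` must be a finite interval with min < max")
  }
  band
}
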