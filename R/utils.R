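# Shared vocabulary and small internal helpers.

#' Behaviour, species and group vocabularies
#'
#' The five analysed behaviour categories are vigilant (`V`), foraging (`F`),
#' locomotion (`L`), resting (`R`) and playing (`P`). `OOS` (out-of-sight) and
#' `OTHER` are valid record tokens but never enter any statistic: an
#' out-of-sight individual contributes nothing to a scan, and activities
#' outside the five analysed categories are excluded everywhere (weights,
#' synchrony index, correlations).
#'
#' @return `analysed_behaviours()` returns a character vector of length 5;
#'   `behaviour_codes()` the full 7-token vocabulary; `species_levels()` and
#'   `group_levels()` the accepted species and group tokens.
#' @export
analysed_behaviours <- function() c("V", "F", "L", "R", "P")

#' @rdname analysed_behaviours
#' @export
behaviour_codes <- function() c(analysed_behaviours(), "OOS", "OTHER")

#' @rdname analysed_behaviours
#' @export
species_levels <- function() c("capuchin", "squirrel")

#' @rdname analysed_behaviours
#' @export
group_levels <- function() c("west", "east")

enclosure_levels <- function() c("indoor", "outdoor")

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# `seed = NULL` uses (and advances) the current stream.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministically expand one master seed into named per-stage substream
# seeds so stages can be rerun independently. Seeds stay below 2^31.
expand_seed <- function(seed, stages) {
  if (is.null(seed)) {
    return(setNames(rep(list(NULL), length(stages)), stages))
  }
  sub <- with_preserved_seed(seed, sample.int(.Machine$integer.max, length(stages)))
  setNames(as.list(sub), stages)
}

abort_schema <- function(msg, ...) {
  abort(msg, class = "scansync_schema_error", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "scansync_validation_error", ...)
}

abort_not_computable <- function(msg, ...) {
  abort(msg, class = "scansync_not_computable", ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
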