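#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2 pmap imap
#' @importFrom stats predict rnorm runif rpois rbinom pbinom sd median
#'   quantile t.test qnorm dist complete.cases setNames
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library code never clobbers the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of one experiment seed into independent per-stage
#' seeds. Uses a Weyl-style integer hash on the stage name; results stay in
#' `[0, 2^31 - 2]` so they are always valid R seeds.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

# consistent failure helper: all exported functions abort with class
# "deltamarch_error" so callers can trap pipeline failures uniformly
dm_abort <- function(message, ...) {
  abort(message, class = "deltamarch_error", ...)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
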