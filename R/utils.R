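#' Derive a deterministic sub-seed for a named stage
#'
#' One global seed drives every stochastic stage of the pipeline; each stage
#' draws from its own stream identified by a label, so that adding draws to
#' one stage never perturbs another.  The sub-seed is a deterministic hash of
#' the label folded into the global seed, kept below `2^31 - 1`.
#'
#' @param seed integer global seed.
#' @param label character stage name.
#' @return An integer seed.
#' @export
#' @examples
#' sub_seed(1, "bootstrap")
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147480009
  as.integer((abs(as.integer(seed)) %% 65521 * 32749 + h) %% 2147483647L)
}

# internal: run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# internal: stop with a prefixed format error
format_error <- function(...) stop(sprintf(...), call. = FALSE)

# internal: %||%
`%||%` <- function(a, b) if (is.null(a)) b else a
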