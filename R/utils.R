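#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in the pipeline flows from one user seed. Each stage draws
#' from its own substream whose seed is a deterministic hash of the stage name
#' combined with the master seed, so adding or reordering stages never
#' perturbs the draws of the others.
#'
#' @param seed Master integer seed.
#' @param name Character tag of the stage (e.g. "genotypes").
#' @return An integer in [0, 2^31 - 1].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_if_not_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", what), call. = FALSE)
  }
  invisible(x)
}
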