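#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' then restores the previous RNG state so that callers' random streams are
#' unaffected. All stochastic generators in the package route their
#' randomness through this helper, which is what makes runs reproducible
#' from a seed alone.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific 32-bit sub-seed from a master seed. Keeps
# independent stages (noise, Bernoulli draws, latencies ...) decoupled.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 69069L + as.integer(stream) * 104729L) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mea <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
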