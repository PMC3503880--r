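#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded package functions do not disturb the
#' user's random stream.
#'
#' @param seed Integer scalar seed (must be < 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  })
  set.seed(as.integer(seed))
  code
}

# Round half away from zero (deterministic event remapping; R's round()
# uses banker's rounding).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Length of the longest run of identical values.
max_run_length <- function(x) {
  if (length(x) == 0L) return(0L)
  max(rle(as.character(x))$lengths)
}

# Derive a set of named per-stage seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, names) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max, length(names))
    names(s) <- names
    s
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
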