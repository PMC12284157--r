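# Internal utilities: seeded RNG scoping and per-stage seed derivation.

# Evaluate expr with a local RNG state seeded by `seed`; the caller's RNG
# state is untouched. All exported stochastic functions funnel through this
# so results are deterministic given (params, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive an independent sub-seed from a master seed and a stage label
#'
#' Expands one user-facing seed into per-stage streams so that toggling one
#' pipeline stage does not perturb another stage's draws. The result is a
#' deterministic integer in `[1, 2^31 - 2]`.
#'
#' @param seed master seed (integer).
#' @param tag character label of the stage/consumer.
#' @param index optional extra integer discriminator (e.g. replicate number).
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  s <- (abs(as.numeric(seed)) %% m)
  out <- (s * 48271 + h * 16807 + as.numeric(index) * 69621 + 1) %% m
  as.integer(out %/% 1 + 1)
}

# simple argument checks
assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
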