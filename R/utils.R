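#' @keywords internal
"_PACKAGE"

# Run code with a local RNG state seeded from an explicit integer, restoring
# the caller's RNG afterwards. Every stochastic operation in the package goes
# through this; there is no reliance on global random state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- abs(seed) %% 2147483647  # keep derived seeds inside integer range
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
  force(code)
}

#' Derive per-module seeds from a master seed
#'
#' Deterministically expands one master seed into `n` child seeds, all below
#' 2^31, so that each stochastic stage of a study gets an independent,
#' reproducible stream.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  # Lehmer multiplicative stream; products stay below 2^53 so the
  # double-precision arithmetic is exact. Seeds lie in [1, 2^31 - 2].
  x <- (as.double(master) %% 2147483646) + 1
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- (x * 48271) %% 2147483647
    out[i] <- as.integer(x)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
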