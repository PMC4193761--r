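# Internal helpers.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic stages of the package go
# through this so that builds, distortions and simulations are reproducible
# and composable without clobbering user RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Deterministic derived seed for sweep cells / repetitions, kept within the
# 32-bit integer range.
derive_seed <- function(master, ...) {
  parts <- c(master, unlist(list(...)))
  h <- 0
  for (p in parts) {
    # multiplier and reduction chosen so every intermediate stays below
    # 2^53: (h %% 67108859) * 67108879 < 4.6e15
    h <- ((h %% 67108859) * 67108879 + as.double(p) + 12345) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
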