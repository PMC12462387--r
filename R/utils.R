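# Internal helpers: reproducible RNG scoping and deterministic seed splitting.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state, so that seeded package internals never clobber the user's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
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

#' Derive a child seed from a parent seed and a string key
#'
#' FNV-1a style hash over the decimal seed and the key, reduced mod 2^31 - 1.
#' Stable across platforms and R versions (pure integer arithmetic on
#' doubles below 2^53), so per-region streams survive region reordering.
#'
#' @param seed parent integer seed.
#' @param key character scalar (e.g. a region id or stage tag).
#' @return integer in [1, 2^31 - 2].
#' @export
split_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.character(key), length(key) == 1L)
  bytes <- utf8ToInt(paste0(format(seed, scientific = FALSE), "::", key))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

# xor for non-negative doubles < 2^31 without integer overflow
bitwXor_dbl <- function(a, b) {
  r <- 0
  p <- 1
  while (a > 0 || b > 0) {
    ra <- a %% 2
    rb <- b %% 2
    if (ra != rb) r <- r + p
    a <- (a - ra) / 2
    b <- (b - rb) / 2
    p <- p * 2
  }
  r
}

#' FNV-1a hash of a character string (hex digest)
#'
#' Used for run manifests to fingerprint configurations.
#'
#' @param x character scalar.
#' @return 8-character lowercase hex string.
#' @keywords internal
fnv1a_hex <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
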