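#' Derive a reproducible child seed
#'
#' Deterministically folds a master seed with any number of keys (integers or
#' strings) into a new seed in `[1, 2^31 - 2]`. Used throughout the package to
#' fan one master seed out to per-subject, per-method and per-repeat seeds so
#' that every stochastic stage is independently reproducible.
#'
#' @param seed Master seed (single integer).
#' @param ... Keys mixed into the seed; character keys are folded bytewise.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "subject", 3)
derive_seed <- function(seed, ...) {
  m <- 2147483647
  x <- as.numeric(seed) %% m
  for (key in list(...)) {
    ks <- if (is.character(key)) as.numeric(utf8ToInt(key)) else as.numeric(key)
    for (k in ks) {
      # Lehmer-style multiplicative mix; stays inside 32-bit integer range
      x <- (x * 48271 + abs(k) + 1) %% m
    }
  }
  as.integer(x %% (m - 2L) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
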