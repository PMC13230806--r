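#' @keywords internal
"_PACKAGE"

## Deterministic seed substreams: one global seed fans out to named stage
## seeds so stages can be rerun independently with identical randomness.
## Must stay below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) stop(sprintf("'%s' must lie in [%g, %g%s", name, lo, hi,
                        if (hi_open) ")" else "]"), call. = FALSE)
  invisible(x)
}
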