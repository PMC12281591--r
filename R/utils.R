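# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
msg <- function(...) message("sigscreen | ", ...)

#' @keywords internal
warn <- function(...) warning("sigscreen | ", ..., call. = FALSE)

stop_fmt <- function(...) stop("sigscreen: ", ..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

assert_prob <- function(p, what) {
  bad <- !is.finite(p) | p <= 0 | p > 1
  if (any(bad)) {
    stop_fmt(what, " must lie in (0, 1]; offending value: ",
             format(p[which(bad)[1L]]))
  }
  invisible(p)
}

#' Derive a reproducible sub-seed from a global seed and a string key
#'
#' Combines an integer seed with a stable polynomial hash of a key string, so
#' that independent random stages (permutation nulls, library simulation,
#' background sampling) are reproducible and order-independent. The result is
#' always a valid 32-bit R seed.
#'
#' @param seed Integer global seed.
#' @param key Character scalar naming the consumer (e.g. "null_size_100").
#' @return A single integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

# Draw one integer uniformly from [range[1], range[2]] (sample() would
# misread a scalar first argument).
sample_range <- function(range) {
  if (range[1L] == range[2L]) return(as.integer(range[1L]))
  sample(seq(range[1L], range[2L]), 1L)
}

# Fixed-point / scientific formatting used by all writers: scores at 6
# decimals, probabilities at 6 significant digits (p-values at e-100 scale
# must survive a round-trip).
fmt_score <- function(x) sprintf("%.6f", x)
fmt_p <- function(x) sprintf("%.6g", x)
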