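# RNG plumbing shared across modules.

#' Derive a reproducible substream seed
#'
#' Expands one global seed into independent per-stage seeds so that adding a
#' stage (or another simulated pair) does not perturb the random draws of
#' earlier stages. Purely arithmetic; the result is always a valid 32-bit
#' integer seed.
#'
#' @param seed Integer scalar, the global seed.
#' @param ... Further integer or character stage labels mixed into the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "pairs", 7)
substream_seed <- function(seed, ...) {
  m <- 2147483629              # large prime < 2^31
  h <- as.double(seed) %% m
  for (part in list(...)) {
    if (is.character(part)) part <- sum(utf8ToInt(part) * seq_along(utf8ToInt(part)))
    for (p in part) h <- (h * 69069 + as.double(p) + 1) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream;
# a NULL seed just uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
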