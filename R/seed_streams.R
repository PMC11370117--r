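# Named random-number streams.
#
# All simulator randomness flows from one base seed through named streams so
# that, e.g., adding clones to a configuration does not perturb the draws of
# earlier clones. A stream is identified by the base seed plus a path of
# labels ("clone", 3, "tree"); the path is hashed to a 31-bit seed.

#' Derive a deterministic sub-seed from a base seed and a label path
#'
#' @param seed integer base seed.
#' @param ... labels (character or integer) identifying the stream.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @keywords internal
stream_seed <- function(seed, ...) {
  mod <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed %% mod)
  for (part in list(...)) {
    for (code in utf8ToInt(paste0("/", as.character(part)))) {
      h <- (h * 31 + code) %% mod
    }
  }
  as.integer(h %% (mod - 1) + 1)
}

#' Evaluate an expression under a named random stream
#'
#' Sets the RNG to the stream's seed for the duration of `expr`, restoring
#' the caller's RNG state afterwards.
#' @keywords internal
with_stream <- function(seed, ..., expr) {
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
  set.seed(stream_seed(seed, ...))
  expr
}
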