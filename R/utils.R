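#' @importFrom rlang abort warn %||%
#' @importFrom stats qnorm pt quantile rnorm runif rbinom var sd median fft
#'   mvfft pnorm p.adjust aov model.matrix reformulate binomial predict
#'   setNames complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All public generators funnel through this
# so outputs are pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L) + 1L
}

clamp01 <- function(x) pmin(1, pmax(0, x))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}
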