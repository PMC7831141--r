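# internal helpers shared across modules

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All public generators funnel through this so a
# fixed seed gives bit-identical output regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# Deterministic per-stage seed derivation from a single top-level seed.
# Keeps results < 2^31 so the value is a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.double(seed) * 7919 + h) %% 2147483629)
}

#' Truncate numbers to a fixed number of decimals
#'
#' Drops decimal digits beyond `digits` without rounding (truncation toward
#' zero). This is the convention that reproduces the published per-condition
#' oxygenation table: every printed \% O2 value equals the computed value with
#' the excess digits cut, not rounded (e.g. 16.0079 prints as 16.00 and
#' 4.2508 prints as 4.2).
#'
#' @param x numeric vector.
#' @param digits integer, decimals to keep (default 2).
#' @return numeric vector truncated to `digits` decimals.
#' @examples
#' truncate_decimals(c(16.0079, 4.2508, -1.236), 2)
#' @export
truncate_decimals <- function(x, digits = 2) {
  p <- 10^digits
  trunc(x * p) / p
}

# Half-up rounding (R's round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_positive_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be finite and > 0", call. = FALSE)
  }
  invisible(x)
}
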