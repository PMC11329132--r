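#' @keywords internal
"_PACKAGE"

# Clip values into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half away from zero
#'
#' Deterministic scalar rounding used everywhere a real value becomes an
#' integer stored value. Unlike [base::round()] (banker's rounding), halves
#' always move away from zero, so results do not depend on the parity of the
#' integer part.
#'
#' @param x numeric vector/array.
#' @return numeric of the same shape, integral values.
#' @export
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Derive a stage-specific RNG seed from one global seed
#'
#' A stable hash of the stage name keeps pipeline stages decorrelated while
#' a single seed knob reproduces a whole run. The result is a non-negative
#' integer below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (v in utf8ToInt(as.character(stage))) h <- (h * 131 + v) %% 1000003
  as.integer((as.numeric(seed) %% 1000003) * 1009 + h) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
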