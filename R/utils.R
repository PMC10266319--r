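`%||%` <- function(x, y) if (is.null(x)) y else x

#' Clamp numeric values to an interval
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the nearest bound.
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## log(1 - exp(a)) for a < 0, stable near both ends
.log1mexp <- function(a) {
  out <- a
  small <- !is.na(a) & a > -0.693147180559945 # -log(2)
  big <- !is.na(a) & !small
  out[small] <- log(-expm1(a[small]))
  out[big] <- log1p(-exp(a[big]))
  out
}

## Deterministic per-arm child seed: a polynomial hash of the arm label mixed
## with the root seed, kept below 2^31 so set.seed() accepts it.  Inserting a
## new arm never perturbs the draws of existing arms.
.arm_child_seed <- function(root_seed, arm) {
  h <- 0
  for (cp in utf8ToInt(as.character(arm))) h <- (h * 31 + cp) %% 2147483587
  as.integer((as.numeric(root_seed) %% 2147483647 + h) %% 2147483647)
}

.assert <- function(cond, ...) if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x > 0 && x == round(x)
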