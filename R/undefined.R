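#' Undefined coefficient values
#'
#' Degenerate tables are common in small agreement studies: if neither
#' observer ever uses a category, the specific agreement for that category
#' has a zero denominator and no meaningful value. Rather than silently
#' returning `NaN` or `0`, coefficient functions return `NA_real_` carrying a
#' `reason` attribute explaining which quantity was degenerate.
#' `undefined_reason()` retrieves it and `is_undefined()` tests for it.
#'
#' @param x A value returned by a coefficient function.
#' @return `is_undefined()` returns a logical scalar; `undefined_reason()`
#'   returns the reason string or `NA_character_`.
#' @examples
#' t <- pair_table(0, 0, 0, 10)
#' ppos_pair(t)           # undefined: no positive ratings
#' is_undefined(ppos_pair(t))
#' undefined_reason(ppos_pair(t))
#' @export
is_undefined <- function(x) {
  length(x) == 1L && is.na(x) && !is.null(attr(x, "reason"))
}

#' @rdname is_undefined
#' @export
undefined_reason <- function(x) {
  r <- attr(x, "reason")
  if (is.null(r)) NA_character_ else r
}

undefined_coef <- function(reason) {
  structure(NA_real_, reason = reason)
}

# strip attributes from defined values so arithmetic stays clean
as_coef <- function(x) as.numeric(x)
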