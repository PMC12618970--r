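#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (5.5 -> 6, -5.5 -> -6),
#' matching the convention used for printed percentages in monitoring reports.
#' Base [round()] uses round-half-even, which is unsuitable for reproducing
#' published tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up (away from zero) to `digits` places.
#' @examples
#' round_half_up(23.805, 2) # 23.81
#' round_half_up(0.125, 2)  # 0.13 (base round() would give 0.12)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# stop() with a call.-free, sprintf-style message
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
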