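#' Round half away from zero
#'
#' Deterministic "school" rounding (0.005 -> 0.01) used for all reported
#' percentages, as opposed to [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a total, rounded to two decimals
#'
#' Central formatting rule for every reported proportion: `100 * n / total`
#' rounded half-up to `digits` decimals. A zero (or missing) total yields
#' `NA` rather than 0/0.
#'
#' @param n numerator count(s).
#' @param total denominator count(s).
#' @param digits decimal places (default 2).
#' @return numeric vector of percentages.
#' @examples
#' pct(17691, 23516) # 75.23
#' @export
pct <- function(n, total, digits = 2) {
  out <- round_half_up(100 * n / total, digits)
  out[!is.finite(rep(total, length.out = length(out))) |
        rep(total, length.out = length(out)) == 0] <- NA_real_
  out
}

# internal: stop() with sprintf formatting
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# internal: scalar integer check
is_count <- function(x, min = 0) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}
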