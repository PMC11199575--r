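# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used for presentation of heart-rate values: halves are
#' rounded away from zero (so 196.5 -> 197, -196.5 -> -197), unlike base
#' [round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_ivret <- function(...) stop(..., call. = FALSE)

# mean +/- t-based 95% CI helper
ci_mean <- function(x, conf = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(c(mean = m, lo = NA_real_, hi = NA_real_))
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}
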