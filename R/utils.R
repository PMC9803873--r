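# Internal helpers shared across modules.

#' Wrap hour differences to the half-open interval (-period/2, period/2]
#' @noRd
wrap_half_period <- function(d, period = 24) {
  m <- d %% period
  m[m > period / 2] <- m[m > period / 2] - period
  m
}

#' Circular absolute difference in hours, in [0, period/2]
#' @noRd
circ_abs_diff <- function(a, b, period = 24) {
  abs(wrap_half_period(a - b, period))
}

#' Angular frequency for a period in hours
#' @noRd
omega_for <- function(period) 2 * pi / period

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
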