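#' @importFrom stats rbinom rpois rnbinom rbeta runif pchisq setNames
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding where ties go up (`2.665 -> 2.67`), as used for the
#' burden percentages, rather than banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Thin wrapper kept package-internal so simulators never clobber the
# session RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == trunc(x)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("modscreen_config_error",
                                             "error", "condition")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("modscreen_format_error",
                                             "error", "condition")))
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("modscreen_domain_error",
                                             "error", "condition")))
}
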