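# Physical constants and small shared helpers.

#' Physical constants used throughout the package
#'
#' Faraday constant (C mol-1) and molar gas constant (J mol-1 K-1).
#'
#' @keywords internal
#' @name constants
NULL

.FARADAY <- 96485
.GAS_CONST <- 8.3145

#' Seconds in a day (rate-unit conversions between s-1 and d-1)
#' @keywords internal
.SECONDS_PER_DAY <- 86400

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a specific rate from s-1 to d-1
#' @param x numeric rate(s) in s-1
#' @return numeric rate(s) in d-1
#' @export
per_day <- function(x) x * .SECONDS_PER_DAY

#' Convert a specific rate from d-1 to s-1
#' @param x numeric rate(s) in d-1
#' @return numeric rate(s) in s-1
#' @export
per_second <- function(x) x / .SECONDS_PER_DAY

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# named numeric vector -> data.frame(id, value)
nv_to_df <- function(x, names = c("id", "value")) {
  d <- data.frame(names(x), as.numeric(x), stringsAsFactors = FALSE)
  names(d) <- names
  d
}
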