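#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used for
#' reported fold changes (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector; infinite and missing values pass through.
#' @examples
#' round_half_up(13.625, 2)  # 13.63
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  out <- sign(x) * floor(abs(x) * f + 0.5) / f
  out[!is.finite(x)] <- x[!is.finite(x)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
warn_ <- function(...) warning(..., call. = FALSE)

# membership signature used to match clusters across trees
.sig <- function(labels) paste(sort(labels), collapse = "\r")
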