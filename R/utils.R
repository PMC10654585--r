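#' Round half away from zero
#'
#' Base R's [round()] rounds half to even ("banker's rounding"), which does
#' not reproduce the half-up convention used throughout the package's
#' tabulated percentages (e.g. 56.25 -> 56.3 at one decimal). This helper
#' rounds halves away from zero. A guard of 1e-9 absorbs binary
#' floating-point representation error in quantities such as `x/n * 100`.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half-up (away from zero).
#' @examples
#' round_half_up(56.25, 1)  # 56.3
#' round(56.25, 1)          # 56.2 (banker's)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## internal: stop with a classed condition so callers/tests can discriminate
stop_hostspec <- function(msg, class) {
  stop(structure(
    class = c(class, "hostspec_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
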