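#' @importFrom stats median fft splinefun lm coef cor pt approx var sd ar
#' @importFrom utils head tail write.csv
NULL

#' Parse a time-of-day into seconds since midnight
#'
#' Accepts "HH:MM", "HH:MM:SS" or a numeric number of seconds (taken modulo
#' 24 h). Sample 0 of a record carries this clock time; all analysis windows
#' are defined in clock time.
#'
#' @param x character time of day or numeric seconds since midnight.
#' @return numeric seconds since midnight in `[0, 86400)`.
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) return(x %% 86400)
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (!length(parts) %in% c(2L, 3L) || anyNA(suppressWarnings(as.numeric(parts))))
    stop("cannot parse clock time: '", x, "'", call. = FALSE)
  parts <- as.numeric(parts)
  (parts[1] * 3600 + parts[2] * 60 + if (length(parts) == 3L) parts[3] else 0) %% 86400
}

#' Format seconds since midnight as "HH:MM:SS"
#' @param s numeric seconds since midnight.
#' @return character vector.
#' @export
format_clock <- function(s) {
  s <- round(s %% 86400)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

# Median with mean-of-middle-two convention for even counts (stats::median
# already does this; kept as a named wrapper so the convention is greppable).
median_mid <- function(x) stats::median(x)

# Population (1/n) variance; the closed-form Poincare descriptors use it.
var_pop <- function(x) mean((x - mean(x))^2)

# Stop with a configuration error naming the offending field.
cfg_stop <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
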