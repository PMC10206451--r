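#' @importFrom rlang %||% abort warn inform
#' @importFrom stats rnorm runif rexp sd setNames
#' @importFrom utils head tail
NULL

#' Round a percentage half-up to an integer
#'
#' Percentages in summaries are reported as integers rounded half-up
#' (0.5 always rounds away from zero for the non-negative shares used
#' here), the convention behind printed values such as 53% for 31/59.
#'
#' @param n numerator (count).
#' @param d denominator (count). `d = 0` yields `NA`.
#' @return integer percentage.
#' @export
pct_int <- function(n, d) {
  out <- floor(n / d * 100 + 0.5)
  out[rep_len(d, length(out)) <= 0] <- NA_real_
  as.integer(out)
}

# half-up integer rounding of a plain number
round_half_up <- function(x) floor(x + 0.5)

assert_that <- function(ok, msg, class = "fishwolf_error") {
  if (!isTRUE(ok)) rlang::abort(msg, class = class)
  invisible(TRUE)
}

# inclusive day count between two Date endpoints
inclusive_days <- function(start, end) {
  as.integer(as.Date(end) - as.Date(start)) + 1L
}

is_night_hour <- function(hour, night_window = c(20L, 6L)) {
  from <- night_window[[1]]
  to <- night_window[[2]]
  if (from > to) hour >= from | hour < to else hour >= from & hour < to
}
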