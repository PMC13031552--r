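# Round half away from zero at d decimal places. Display rounding only;
# stored fractions are never rounded.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Format a probability as a reciprocal "1 in x" string
#'
#' Renders a frequency the way burden tables print it. Two styles:
#'
#' * `style = "gene"` — per-gene carrier frequencies and prevalences:
#'   integer `x` below 1000, then thousand (`K`) and million (`M`) suffixes
#'   with one decimal kept while the scaled value is below 10 (e.g.
#'   `"1 in 2.1K"`, `"1 in 147M"`); a trailing `.0` is dropped (`"1 in 8K"`).
#' * `style = "group"` — disease-group prevalences: two decimals while
#'   `x < 10` (e.g. 37.0% renders as `"1 in 2.70"`), integer above.
#'
#' Rounding is half-up at the displayed precision. `parse_one_in()` inverts
#' the rendering to display precision.
#'
#' @param p Numeric vector of probabilities in (0, 1].
#' @param style `"gene"` or `"group"`.
#' @return Character vector of `"1 in x"` strings.
#' @export
#' @examples
#' format_one_in(0.370, "group")    # "1 in 2.70"
#' format_one_in(1 / 2100, "gene")  # "1 in 2.1K"
format_one_in <- function(p, style = c("gene", "group")) {
  style <- match.arg(style)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must lie in (0, 1]")
  }
  x <- 1 / p
  if (style == "group") {
    out <- ifelse(x < 10,
                  sprintf("%.2f", round_half_up(x, 2)),
                  sprintf("%d", as.integer(round_half_up(x))))
    return(paste("1 in", out))
  }
  fmt_scaled <- function(u) {
    # one decimal below 10, integer above; drop a trailing ".0"
    s <- ifelse(u < 10, sprintf("%.1f", round_half_up(u, 1)),
                sprintf("%d", as.integer(round_half_up(u))))
    sub("\\.0$", "", s)
  }
  out <- character(length(x))
  lo <- x < 1000
  md <- x >= 1000 & x < 1e6
  hi <- x >= 1e6
  out[lo] <- sprintf("%d", as.integer(round_half_up(x[lo])))
  out[md] <- paste0(fmt_scaled(x[md] / 1e3), "K")
  out[hi] <- paste0(fmt_scaled(x[hi] / 1e6), "M")
  paste("1 in", out)
}

#' Parse a "1 in x" string back to a probability
#'
#' Inverse of [format_one_in()] at display precision: `"1 in 2.1K"` gives
#' `1/2100`, `"1 in 2.70"` gives `1/2.70`.
#'
#' @param s Character vector of `"1 in x"` strings.
#' @return Numeric vector of probabilities.
#' @export
parse_one_in <- function(s) {
  m <- regmatches(s, regexec("^1 in ([0-9.]+)([KM]?)$", s))
  vapply(m, function(g) {
    if (length(g) == 0) stop("not a '1 in x' string")
    mult <- switch(g[3], K = 1e3, M = 1e6, 1)
    1 / (as.numeric(g[2]) * mult)
  }, numeric(1))
}
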