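#' Unit conversions at the I/O boundary
#'
#' The package works in SI units internally (metres, seconds, pascals,
#' kilograms). Microlitres and minutes appear only in user-facing tables and
#' files; these helpers perform the conversions explicitly.
#'
#' @param x Numeric vector.
#' @return Numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
ul_to_m3 <- function(x) x * 1e-9

#' @rdname units
#' @export
m3_to_ul <- function(x) x * 1e9

#' @rdname units
#' @export
min_to_s <- function(x) x * 60

#' @rdname units
#' @export
s_to_min <- function(x) x / 60

#' @rdname units
#' @export
ul_min_to_m3_s <- function(x) x * 1e-9 / 60

#' @rdname units
#' @export
m3_s_to_ul_min <- function(x) x * 1e9 * 60

# percentages rounded half-away-from-zero, as in the study's reporting
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
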