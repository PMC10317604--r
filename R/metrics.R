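#' Plasma purity from cell counts
#'
#' Purity of the separated plasma with respect to one analyte:
#' \deqn{\mathrm{purity} = 1 - \frac{\mathrm{count~in~output}}{\mathrm{count~in~input}}.}
#' The value is clamped upward only on exact floating underflow; an output
#' count exceeding the input yields a warning and an unclamped negative
#' value, which signals a data problem rather than being silently hidden.
#'
#' @param input_count Analyte concentration in the feed (per ul), > 0.
#' @param output_count Analyte concentration in the separated plasma
#'   (per ul), >= 0.
#' @return Purity fraction, at most 1.
#' @examples
#' plasma_purity(4.42e6, 4.34e4)  # red-cell purity ~ 0.99
#' @export
plasma_purity <- function(input_count, output_count) {
  if (any(input_count <= 0)) stop_domain("input_count must be > 0")
  if (any(output_count < 0)) stop_domain("output_count must be >= 0")
  if (any(output_count > input_count)) {
    warn("output count exceeds input count; returning a negative purity")
  }
  p <- 1 - output_count / input_count
  ifelse(p < 0 & p > -1e-15, 0, p)
}

#' Plasma recovery as a percentage of the available plasma
#'
#' The collected volume relative to the plasma content of the injected
#' sample, \eqn{100\, V_{collected} / (V_{injected} (1 - \mathrm{HCT}))}.
#' With `hct_mode = "rounded"` the hematocrit is first rounded
#' half-away-from-zero to the nearest percent, the convention used for the
#' device's headline figure (0.399 becomes 0.40, giving a plasma fraction of
#' 0.60); `"exact"` uses the hematocrit as given. The mode in use is
#' reported via `message()` so that the convention is always visible.
#'
#' @param collected_ul Collected plasma volume, ul.
#' @param injected_ul Injected whole-blood volume, ul (> 0).
#' @param hematocrit Red-cell volume fraction in \[0, 1).
#' @param hct_mode `"exact"` or `"rounded"`.
#' @param quiet Suppress the convention message.
#' @return Recovery in percent (not rounded).
#' @examples
#' recovery_fraction(3.5, 10, 0.399, hct_mode = "rounded")  # 58.33...
#' @export
recovery_fraction <- function(collected_ul, injected_ul, hematocrit,
                              hct_mode = c("exact", "rounded"),
                              quiet = FALSE) {
  hct_mode <- match.arg(hct_mode)
  if (injected_ul <= 0) stop_domain("injected_ul must be > 0")
  if (hematocrit < 0 || hematocrit >= 1) stop_domain("hematocrit must lie in [0, 1)")
  if (collected_ul < 0) stop_domain("collected_ul must be >= 0")
  h <- if (hct_mode == "rounded") round_half_away(hematocrit, 2) else hematocrit
  if (!quiet) {
    message(sprintf("recovery_fraction: %s-HCT mode (plasma fraction %.3f)",
                    hct_mode, 1 - h))
  }
  available <- injected_ul * (1 - h)
  if (collected_ul > available) {
    warn("collected volume exceeds the available plasma; check for dilution or measurement error")
  }
  100 * collected_ul / available
}

#' Coefficient of determination between experiment and model
#'
#' \deqn{R^2 = \frac{\sum_i (x_{i,exp} - \bar{x})^2 - \sum_i (x_{i,exp} - x_{i,model})^2}
#'                  {\sum_i (x_{i,exp} - \bar{x})^2}}
#' with \eqn{\bar{x}} the mean of the experimental values; algebraically
#' identical to \eqn{1 - SS_{res}/SS_{tot}}.
#'
#' @param experimental,modelled Numeric vectors of equal length >= 2;
#'   `experimental` must not be constant.
#' @return Dimensionless value <= 1.
#' @export
r_squared <- function(experimental, modelled) {
  if (length(experimental) != length(modelled)) {
    stop_domain("series lengths differ")
  }
  if (length(experimental) < 2) stop_domain("need at least 2 points")
  ss_tot <- sum((experimental - mean(experimental))^2)
  if (ss_tot == 0) stop_domain("experimental series is constant (SS_tot = 0)")
  ss_res <- sum((experimental - modelled)^2)
  (ss_tot - ss_res) / ss_tot
}

#' Mean squared error between experiment and model
#'
#' \eqn{\mathrm{MSE} = \sum_i (x_{i,exp} - x_{i,model})^2 / N}.
#'
#' @param experimental,modelled Numeric vectors of equal length N >= 1.
#' @return MSE in squared data units.
#' @export
mse <- function(experimental, modelled) {
  if (length(experimental) != length(modelled)) {
    stop_domain("series lengths differ")
  }
  if (length(experimental) < 1) stop_domain("need at least 1 point")
  mean((experimental - modelled)^2)
}

#' Goodness-of-fit report
#'
#' @param experimental,modelled Numeric vectors of equal length >= 2.
#' @return A `capilsep_fit_report`: list with `r_squared`, `mse`, `n`, and a
#'   `residuals` tibble (`experimental`, `modelled`, `residual`).
#' @export
fit_report <- function(experimental, modelled) {
  structure(list(
    r_squared = r_squared(experimental, modelled),
    mse = mse(experimental, modelled),
    n = length(experimental),
    residuals = tibble(experimental = experimental, modelled = modelled,
                       residual = experimental - modelled)
  ), class = "capilsep_fit_report")
}

#' @export
print.capilsep_fit_report <- function(x, ...) {
  cat(sprintf("<capilsep_fit_report> n = %d, R^2 = %.4f, MSE = %.5f\n",
              x$n, x$r_squared, x$mse))
  invisible(x)
}

#' Purity table for a set of analytes
#'
#' Applies [plasma_purity()] rowwise to a cell-count table. HGB and HCT
#' rows are carried through with a flag: their printed values are not
#' particle counts and the purity number for them is unit-ambiguous.
#'
#' @param counts A data frame with columns `analyte`, `input_value`,
#'   `output_value` (see [read_counts()]).
#' @return A tibble with `analyte`, `input_value`, `output_value`, `purity`,
#'   `purity_pct`, `unit_ambiguous`.
#' @export
purity_by_analyte <- function(counts) {
  stopifnot(all(c("analyte", "input_value", "output_value") %in% names(counts)))
  tibble(
    analyte = counts$analyte,
    input_value = counts$input_value,
    output_value = counts$output_value,
    purity = plasma_purity(counts$input_value, counts$output_value),
    purity_pct = 100 * plasma_purity(counts$input_value, counts$output_value),
    unit_ambiguous = counts$analyte %in% c("HGB", "HCT")
  )
}
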