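#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   facet_wrap theme_minimal
NULL

#' Plot a separation series
#'
#' @param object A `capilsep_series`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.capilsep_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time_min, y = .data$volume_ul,
                     colour = .data$source)) +
    geom_line() + geom_point() +
    labs(x = "time (min)", y = "collected plasma (µl)", colour = NULL) +
    theme_minimal()
}

#' Plot a flow trajectory
#'
#' Meniscus position and flow rate against time.
#'
#' @param object A `capilsep_trajectory`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.capilsep_trajectory <- function(object, ...) {
  st <- object$states
  df <- tibble(
    time_min = rep(s_to_min(st$time), 2),
    value = c(st$meniscus_position * 1e3, m3_s_to_ul_min(st$flow_rate)),
    what = rep(c("meniscus position (mm)", "flow rate (µl/min)"),
               each = nrow(st))
  )
  ggplot(df, aes(x = .data$time_min, y = .data$value)) +
    geom_line() +
    facet_wrap(~what, scales = "free_y", ncol = 1) +
    labs(x = "time (min)", y = NULL) +
    theme_minimal()
}

#' Plot a concentration field
#'
#' Plasma mass fraction along the filled domain.
#'
#' @param object A `capilsep_field`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.capilsep_field <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$x_m * 1e3, y = .data$omega_plasma)) +
    geom_line() +
    labs(x = "arc length (mm)", y = "plasma mass fraction ω") +
    theme_minimal()
}

#' Plot a calibration result
#'
#' Observations against the calibrated model curve.
#'
#' @param object A `capilsep_calibration`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.capilsep_calibration <- function(object, ...) {
  s <- object$model$series
  obs <- object$observations
  ggplot() +
    geom_line(data = s, aes(x = .data$time_min, y = .data$volume_ul),
              colour = "steelblue") +
    geom_point(data = obs, aes(x = .data$time_min, y = .data$volume_ul),
               colour = "black", size = 2) +
    labs(x = "time (min)", y = "collected plasma (µl)",
         title = sprintf("model vs observations (R² = %.3f)",
                         object$fit$r_squared)) +
    theme_minimal()
}
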