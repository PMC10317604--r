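# tunable model parameters: how each maps onto a chip configuration
param_defs <- function() {
  tibble(
    name = c("tau_c", "D_f", "theta_philic", "theta_phobic", "eps_cells"),
    lower = c(120, 1e-13, 15, 91, 0),
    upper = c(7200, 1e-8, 85, 160, 1),
    init = c(900, 1e-10, 40, 110, 0.0098),
    log_scale = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

set_params <- function(config, par) {
  for (nm in names(par)) {
    v <- par[[nm]]
    if (nm == "tau_c") {
      config$fluid$coagulation_tau <- v
    } else if (nm == "D_f") {
      for (i in seq_along(config$species)) config$species[[i]]$diffusivity <- v
    } else if (nm == "theta_philic") {
      for (i in seq_along(config$segments)) {
        if (config$segments[[i]]$wettability_zone == "hydrophilic_coated") {
          config$segments[[i]]$contact_angle <- v
        }
      }
    } else if (nm == "theta_phobic") {
      for (i in seq_along(config$segments)) {
        if (config$segments[[i]]$wettability_zone == "hydrophobic_band") {
          config$segments[[i]]$contact_angle <- v
        }
      }
    } else if (nm == "eps_cells") {
      for (i in seq_along(config$species)) {
        if (config$species[[i]]$name == "cells") {
          config$species[[i]]$barrier_transmission <- v
        }
      }
    } else {
      stop_domain(sprintf("unknown calibration parameter '%s'", nm))
    }
  }
  config
}

#' Specify a model calibration
#'
#' Chooses the free parameters, their box bounds and starting values, and
#' the simulation resolution used inside the objective. The loss is fixed:
#' the mean squared error between observed and modelled collected volumes at
#' the observation times. Defaults free the coagulation time constant
#' `tau_c` and the effective diffusivity `D_f`; contact angles and the cell
#' transmission can be freed instead for identifiability studies.
#'
#' @param free Character vector, subset of `"tau_c"`, `"D_f"`,
#'   `"theta_philic"`, `"theta_phobic"`, `"eps_cells"`.
#' @param lower,upper,init Optional named numeric overrides of the default
#'   bounds/starts (natural units: seconds, m^2/s, degrees, fraction).
#' @param n_cells,dt_max Simulation resolution for objective evaluations
#'   (coarser than reporting resolution; see the methods vignette).
#' @param max_evals Budget of model evaluations for the optimizer.
#' @param reltol Relative convergence tolerance of the objective.
#' @return A `capilsep_calspec` object.
#' @export
calibration_spec <- function(free = c("tau_c", "D_f"), lower = NULL,
                             upper = NULL, init = NULL, n_cells = 120,
                             dt_max = 1, max_evals = 200, reltol = 1e-6) {
  defs <- param_defs()
  bad <- setdiff(free, defs$name)
  if (length(bad)) stop_validation(sprintf("unknown parameter(s): %s",
                                           paste(bad, collapse = ", ")))
  defs <- defs[match(free, defs$name), ]
  override <- function(col, vals) {
    if (is.null(vals)) return(defs[[col]])
    out <- defs[[col]]
    out[match(names(vals), defs$name)] <- unname(vals)
    out
  }
  defs$lower <- override("lower", lower)
  defs$upper <- override("upper", upper)
  defs$init <- override("init", init)
  if (any(!is.finite(defs$lower)) || any(!is.finite(defs$upper)) ||
      any(defs$lower >= defs$upper)) {
    stop_validation("bounds must be finite with lower < upper")
  }
  if (any(defs$init < defs$lower | defs$init > defs$upper)) {
    stop_validation("initial values must lie within the bounds")
  }
  structure(list(params = defs, n_cells = n_cells, dt_max = dt_max,
                 max_evals = max_evals, reltol = reltol),
            class = "capilsep_calspec")
}

# box transform: optimizer coordinate z in R maps into (lower, upper),
# on the log scale where flagged
to_natural <- function(z, defs) {
  lo <- ifelse(defs$log_scale, log(defs$lower), defs$lower)
  hi <- ifelse(defs$log_scale, log(defs$upper), defs$upper)
  v <- lo + (hi - lo) * stats::plogis(z)
  stats::setNames(ifelse(defs$log_scale, exp(v), v), defs$name)
}
to_z <- function(p, defs) {
  lo <- ifelse(defs$log_scale, log(defs$lower), defs$lower)
  hi <- ifelse(defs$log_scale, log(defs$upper), defs$upper)
  v <- ifelse(defs$log_scale, log(p), p)
  stats::qlogis(pmin(pmax((v - lo) / (hi - lo), 1e-12), 1 - 1e-12))
}

#' Calibrate the separation model to observed collected volumes
#'
#' Minimises the mean squared error between the model's collected-plasma
#' curve (interpolated to the observation times by monotone piecewise-linear
#' interpolation) and the observations, over the free parameters of `spec`,
#' using bounded derivative-free local search from the documented fixed
#' start (Nelder-Mead on a logistic box transform; Brent line search when a
#' single parameter is free). Deterministic for identical inputs. The
#' goodness of fit at the optimum is reported as both the coefficient of
#' determination and the MSE.
#'
#' @param config Base `capilsep_chip`.
#' @param observations A data frame with `time_min` and `volume_ul`
#'   (>= 2 rows), e.g. [measured_separation_series()] or
#'   [generate_series()] output.
#' @param spec A [calibration_spec()].
#' @return A `capilsep_calibration` object with elements `par` (named fitted
#'   values), `fit` ([fit_report()]), `converged`, `n_evals`, `model` (the
#'   [run_separation()] result at the optimum), `config` (calibrated chip),
#'   `initial_objective`, `objective`.
#' @export
calibrate <- function(config, observations, spec = calibration_spec()) {
  stopifnot(inherits(config, "capilsep_chip"))
  obs <- as_tibble(observations)
  if (!all(c("time_min", "volume_ul") %in% names(obs)) || nrow(obs) < 2) {
    stop_validation("observations need columns time_min, volume_ul and >= 2 rows")
  }
  defs <- spec$params
  t_end <- max(obs$time_min)
  n_evals <- 0L
  objective_nat <- function(p) {
    n_evals <<- n_evals + 1L
    cfg <- set_params(config, p)
    res <- run_separation(cfg, t_end = t_end, n_cells = spec$n_cells,
                          dt_max = spec$dt_max, start = "primed")
    mse(obs$volume_ul, interpolate_series(res, obs$time_min))
  }
  f0 <- objective_nat(stats::setNames(defs$init, defs$name))

  if (nrow(defs) == 1L) {
    lo <- if (defs$log_scale) log(defs$lower) else defs$lower
    hi <- if (defs$log_scale) log(defs$upper) else defs$upper
    fn <- function(v) {
      objective_nat(stats::setNames(if (defs$log_scale) exp(v) else v, defs$name))
    }
    opt <- stats::optim(par = if (defs$log_scale) log(defs$init) else defs$init,
                        fn = fn, method = "Brent", lower = lo, upper = hi,
                        control = list(reltol = spec$reltol))
    par_hat <- stats::setNames(if (defs$log_scale) exp(opt$par) else opt$par,
                               defs$name)
    converged <- opt$convergence == 0
    f_hat <- opt$value
  } else {
    fn <- function(z) objective_nat(to_natural(z, defs))
    opt <- stats::optim(par = to_z(defs$init, defs), fn = fn,
                        method = "Nelder-Mead",
                        control = list(maxit = spec$max_evals,
                                       reltol = spec$reltol))
    par_hat <- to_natural(opt$par, defs)
    converged <- opt$convergence == 0
    f_hat <- opt$value
  }
  if (f_hat > f0 + 1e-15) {   # descent guard: never worse than the start
    par_hat <- stats::setNames(defs$init, defs$name)
    f_hat <- f0
    converged <- FALSE
  }
  cfg_hat <- set_params(config, par_hat)
  model <- run_separation(cfg_hat, t_end = t_end, n_cells = spec$n_cells,
                          dt_max = spec$dt_max, start = "primed")
  pred <- interpolate_series(model, obs$time_min)
  structure(list(
    par = par_hat,
    fit = fit_report(obs$volume_ul, pred),
    converged = converged,
    n_evals = n_evals,
    model = model,
    config = cfg_hat,
    observations = obs,
    spec = spec,
    initial_objective = f0,
    objective = f_hat,
    extrapolated_completion_time = NULL
  ), class = "capilsep_calibration")
}

#' @export
print.capilsep_calibration <- function(x, ...) {
  cat("<capilsep_calibration> ", if (x$converged) "converged" else "NOT converged",
      " after ", x$n_evals, " model evaluations\n", sep = "")
  for (nm in names(x$par)) cat(sprintf("  %-13s %.6g\n", nm, x$par[[nm]]))
  cat(sprintf("  R^2 = %.4f, MSE = %.5f ul^2\n", x$fit$r_squared, x$fit$mse))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.capilsep_calibration <- function(x, ...) {
  defs <- x$spec$params
  tibble(term = names(x$par), estimate = unname(x$par),
         lower = defs$lower, upper = defs$upper, start = defs$init)
}

#' @exportS3Method generics::glance
glance.capilsep_calibration <- function(x, ...) {
  tibble(r_squared = x$fit$r_squared, mse = x$fit$mse,
         n_obs = x$fit$n, n_evals = x$n_evals, converged = x$converged)
}

#' Time to reach a given separation completeness
#'
#' Runs the calibrated model forward and returns the first time at which
#' the collected plasma reaches `completion_fraction` of the available
#' plasma (injected volume times plasma fraction, with the same hematocrit
#' convention options as [recovery_fraction()]). The crossing time is
#' located by linear interpolation between steps, i.e. to within one time
#' step. If the target is not reached by `cap_min` minutes the function
#' returns `NA` with attribute `reason = "not attained"` -- never a
#' fabricated time.
#'
#' @param config Base `capilsep_chip` (the calibrated parameters of
#'   `result` are applied to it).
#' @param result A `capilsep_calibration`.
#' @param completion_fraction Target fraction(s) in \[0, 1\]; a vector is
#'   served by a single forward run.
#' @param hct_mode `"rounded"` or `"exact"` hematocrit convention for the
#'   available-plasma denominator.
#' @param cap_min Hard simulation cap, minutes.
#' @param dt_max,n_cells Simulation resolution.
#' @return Crossing time in minutes, or `NA` (non-attainment).
#' @export
extrapolate_completion <- function(config, result, completion_fraction = 0.999,
                                   hct_mode = c("rounded", "exact"),
                                   cap_min = 500, dt_max = 1, n_cells = 120) {
  hct_mode <- match.arg(hct_mode)
  stopifnot(inherits(result, "capilsep_calibration"))
  if (!isTRUE(result$converged)) {
    warn("extrapolating from a calibration that did not converge")
  }
  if (any(completion_fraction < 0 | completion_fraction > 1)) {
    stop_domain("completion_fraction must lie in [0, 1]")
  }
  op <- config$operating
  h <- if (hct_mode == "rounded") round_half_away(op$hematocrit, 2) else op$hematocrit
  available <- op$injected_volume_ul * (1 - h)
  cfg <- set_params(config, result$par)
  res <- run_separation(cfg, t_end = cap_min, n_cells = n_cells,
                        dt_max = dt_max, start = "primed")
  s <- res$series
  crossing <- function(target) {
    if (target <= 0) return(0)
    idx <- which(s$volume_ul >= target)
    if (!length(idx)) return(NA_real_)
    i <- idx[1]
    if (i == 1) return(s$time_min[1])
    t0 <- s$time_min[i - 1]; t1 <- s$time_min[i]
    v0 <- s$volume_ul[i - 1]; v1 <- s$volume_ul[i]
    if (v1 > v0) t0 + (target - v0) / (v1 - v0) * (t1 - t0) else t1
  }
  out <- vapply(completion_fraction * available, crossing, numeric(1))
  names(out) <- if (length(out) > 1) format(completion_fraction) else NULL
  if (anyNA(out)) {
    attr(out, "reason") <- "not attained"
    attr(out, "final_volume_ul") <- max(s$volume_ul)
  }
  out
}
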