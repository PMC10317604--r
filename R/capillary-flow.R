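#' Young-Laplace entry pressure of a segment
#'
#' Capillary driving pressure of the meniscus in a segment:
#' \eqn{2\sigma\cos\theta/R} for a cylindrical bore and
#' \eqn{2\sigma\cos\theta(1/w + 1/d)} for a rectangular channel. Positive
#' values drive the wetting liquid forward; a non-wetting segment
#' (\eqn{\theta > 90^\circ}) gives a negative value and acts as a burst
#' barrier.
#'
#' @param segment A [segment()].
#' @param fluid A [fluid_properties()].
#' @return Pressure in Pa.
#' @examples
#' s <- segment("t", "vertical_well", 1e-3, cyl_section(0.5e-3), 60, 90)
#' capillary_pressure(s, fluid_properties(surface_tension = 0.05))  # 100 Pa
#' @export
capillary_pressure <- function(segment, fluid) {
  ct <- cospi(segment$contact_angle / 180)   # exact zero at 90 degrees
  cs <- segment$cross_section
  switch(cs$shape,
    cylindrical = 2 * fluid$surface_tension * ct / cs$radius,
    rectangular = 2 * fluid$surface_tension * ct * (1 / cs$width + 1 / cs$depth)
  )
}

#' Poiseuille resistance of a partially wetted segment
#'
#' Fully developed laminar (lubrication-limit) resistance of the wetted
#' length `filled_length`: \eqn{8\mu L/(\pi R^4)} for a cylindrical bore and
#' \eqn{12\mu L / (w d^3 (1 - 0.63\, d/w))} for a rectangular channel with
#' \eqn{d \le w} (dimensions are swapped if given the other way around).
#' Linear in both `filled_length` and `mu`.
#'
#' @param segment A [segment()].
#' @param filled_length Wetted length in metres, in \[0, segment length\].
#' @param mu Dynamic viscosity, Pa s (> 0).
#' @return Resistance in Pa s/m^3.
#' @export
hydraulic_resistance <- function(segment, filled_length, mu) {
  if (filled_length < 0) stop_domain("filled_length must be >= 0")
  if (mu <= 0) stop_domain("viscosity must be > 0")
  if (filled_length == 0) return(0)
  if (filled_length > segment$length + 1e-12) {
    stop_domain("filled_length exceeds segment length")
  }
  cs <- segment$cross_section
  switch(cs$shape,
    cylindrical = 8 * mu * filled_length / (pi * cs$radius^4),
    rectangular = {
      w <- max(cs$width, cs$depth)
      d <- min(cs$width, cs$depth)
      12 * mu * filled_length / (w * d^3 * (1 - 0.63 * d / w))
    }
  )
}

#' Coagulation-grown effective viscosity
#'
#' The progressive slowdown of passive flow is modelled as an exponential
#' growth of the effective viscosity, \eqn{\mu(t) = \mu_l e^{t/\tau_c}}.
#' `coagulation_tau = Inf` disables the effect.
#'
#' @param fluid A [fluid_properties()].
#' @param t Time since the start of the run, seconds (>= 0).
#' @return Effective viscosity in Pa s.
#' @export
effective_viscosity <- function(fluid, t) {
  if (any(t < 0)) stop_domain("t must be >= 0")
  if (is.infinite(fluid$coagulation_tau)) {
    rep(fluid$viscosity, length(t))
  } else {
    fluid$viscosity * exp(t / fluid$coagulation_tau)
  }
}

#' Flow state at one instant
#'
#' @param config A `capilsep_chip`.
#' @param time Time, seconds.
#' @param position Meniscus arc-length position, metres.
#' @param flow_rate Instantaneous volumetric flow, m^3/s.
#' @param stopped Logical, barrier stop flag.
#' @return A one-row tibble with the state variables (SI units).
#' @export
flow_state <- function(config, time, position, flow_rate = 0, stopped = FALSE) {
  geom <- chip_geometry(config)
  tibble(
    time = time,
    meniscus_position = position,
    filled_volume = geom_cumvol(geom, position),
    flow_rate = flow_rate,
    effective_viscosity = effective_viscosity(config$fluid, time),
    stopped = stopped
  )
}

#' Net driving pressure at the meniscus
#'
#' Capillary entry pressure of the segment the meniscus is in (or entering),
#' minus the hydrostatic head \eqn{\rho_l g \Delta h} of the filled column,
#' where \eqn{\Delta h} follows from the segment inclinations. The loading
#' pump is modelled as a flow source at the inlet and therefore does not
#' appear as a pressure term.
#'
#' @param config A `capilsep_chip`.
#' @param state A [flow_state()] row (uses `meniscus_position`).
#' @return Net pressure in Pa; positive drives the meniscus forward.
#' @export
driving_pressure <- function(config, state) {
  geom <- chip_geometry(config)
  x <- state$meniscus_position[1]
  i <- geom_segment_index(geom, x)
  pc <- capillary_pressure(config$segments[[i]], config$fluid)
  pg <- config$fluid$density * config$fluid$gravity * geom_height(geom, x)
  pc - pg
}

# passive volumetric rate at meniscus position x and time t; Q <= 0 means a
# stopped (or equilibrium) meniscus. x is regularised below x_min.
passive_rate <- function(geom, config, x, t, x_min = 1e-6) {
  x <- max(x, x_min)
  i <- geom_segment_index(geom, min(x, geom$total_length))
  pc <- capillary_pressure(config$segments[[i]], config$fluid)
  pg <- config$fluid$density * config$fluid$gravity * geom_height(geom, x)
  mu <- effective_viscosity(config$fluid, t)
  res <- geom_resistance_unit_mu(geom, x) * mu
  (pc - pg) / res
}

#' Integrate the capillary filling of the chip
#'
#' Solves \eqn{dx/dt = Q/A(x)} with
#' \eqn{Q = \max(0, \Delta P / R_{tot})} through the segment chain using an
#' adaptive explicit Runge-Kutta (Heun) scheme with event detection at
#' segment boundaries. The meniscus stops at a hydrophobic barrier while the
#' net passive pressure is negative. If the metering pump is active the
#' barrier is burst immediately -- a displacement source sustains arbitrary
#' pressure at vanishing rate -- and both the stop and the burst are
#' recorded as events; without a pump a stop is permanent, since the driving
#' pressure is time-independent and the effective viscosity only grows. The
#' trajectory ends at `t_end` or when the meniscus reaches the outlet end.
#' Fully deterministic.
#'
#' @param config A `capilsep_chip`.
#' @param t_end End time in seconds (> 0).
#' @param dt_max Maximum step, seconds.
#' @param x0 Initial wetted length, metres; defaults to the 1 um
#'   regularisation of the startup singularity.
#' @param pos_tol Absolute per-step position tolerance, metres.
#' @return A `capilsep_trajectory`: list with `states` (tibble of time,
#'   meniscus_position, filled_volume, flow_rate, effective_viscosity,
#'   stopped, flux_integral) and `events` (tibble of time, label).
#' @export
advance_flow <- function(config, t_end, dt_max = 0.1, x0 = 1e-6,
                         pos_tol = 1e-7) {
  if (t_end <= 0) stop_domain("t_end must be > 0")
  geom <- chip_geometry(config)
  L <- geom$total_length
  pump <- ul_min_to_m3_s(config$operating$pump_rate_ul_min)
  x <- max(x0, 1e-6)
  t <- 0
  dt <- min(dt_max, 1e-3)
  flux_int <- 0

  # growable state buffers
  cap <- 1024L
  n_rec <- 0L
  b_t <- numeric(cap); b_x <- numeric(cap); b_q <- numeric(cap)
  b_s <- logical(cap); b_f <- numeric(cap)
  rec <- function(tt, xx, qq, ss, ff) {
    if (n_rec == cap) {
      cap <<- cap * 2L
      length(b_t) <<- cap; length(b_x) <<- cap; length(b_q) <<- cap
      length(b_s) <<- cap; length(b_f) <<- cap
    }
    n_rec <<- n_rec + 1L
    b_t[n_rec] <<- tt; b_x[n_rec] <<- xx; b_q[n_rec] <<- qq
    b_s[n_rec] <<- ss; b_f[n_rec] <<- ff
  }
  ev_t <- numeric(0); ev_lab <- character(0)
  push_event <- function(tt, lab) {
    ev_t[[length(ev_t) + 1]] <<- tt
    ev_lab[[length(ev_lab) + 1]] <<- lab
  }

  # realised rate and whether the passive drive is blocked at x
  rate_at <- function(x, t) {
    qp <- passive_rate(geom, config, x, t)
    if (qp > 0) {
      list(q = if (pump > 0) min(qp, pump) else qp, blocked = FALSE)
    } else {
      list(q = if (pump > 0) pump else 0, blocked = TRUE)
    }
  }
  seg_now <- geom_segment_index(geom, x)
  push_event(0, paste0("enter:", geom$id[seg_now]))
  r0 <- rate_at(x, t)
  rec(t, x, r0$q, r0$blocked && pump <= 0, 0)
  barrier_announced <- FALSE

  max_steps <- 5e6
  step <- 0
  while (t < t_end && x < L) {
    step <- step + 1
    if (step > max_steps) {
      abort("flow integration exceeded the step budget",
            class = c("capilsep_integration_error", "capilsep_error"))
    }
    r <- rate_at(x, t)
    if (r$blocked && !barrier_announced) {
      push_event(t, paste0("stop:", geom$id[geom_segment_index(geom, x)]))
      if (pump > 0) {
        push_event(t, paste0("burst:", geom$id[geom_segment_index(geom, x)]))
      }
      barrier_announced <- TRUE
    }
    if (!r$blocked) barrier_announced <- FALSE
    if (r$q <= 0) {
      # permanent passive stop
      t <- t_end
      rec(t, x, 0, TRUE, flux_int)
      break
    }
    dt <- min(dt, t_end - t)
    f1 <- r$q / geom_area_at(geom, min(x, L - 1e-15))
    x_eu <- x + dt * f1
    r_eu <- rate_at(min(x_eu, L), t + dt)
    f2 <- r_eu$q / geom_area_at(geom, min(x_eu, L - 1e-15))
    x_he <- x + dt / 2 * (f1 + f2)
    err <- abs(x_he - x_eu)
    if (err > pos_tol && dt > 1e-9) {
      dt <- max(1e-9, 0.9 * dt * sqrt(pos_tol / max(err, 1e-300)))
      next
    }
    x_new <- x_he
    dt_used <- dt
    clamped <- FALSE
    # clamp at the next segment boundary (event detection); the crossing
    # time follows from the start-of-step speed, which is exact within the
    # constant-area remainder of the segment at constant rate
    bnd <- geom$x1[geom_segment_index(geom, x)]
    crossed_boundary <- FALSE
    if (x_new >= bnd - 1e-15 && bnd < L) {
      dt_used <- max(min(dt, (bnd - x) / max(f1, 1e-300)), 1e-12 * dt)
      x_new <- bnd
      crossed_boundary <- TRUE
      clamped <- TRUE
    }
    if (x_new >= L) {
      dt_used <- max(min(dt, (L - x) / max(f1, 1e-300)), 1e-12 * dt)
      x_new <- L
      clamped <- TRUE
    }
    if (!is.finite(x_new)) {
      abort("non-finite meniscus position during flow integration",
            class = c("capilsep_integration_error", "capilsep_error"),
            body = sprintf("t = %g s, x = %g m", t, x))
    }
    r_new <- rate_at(min(x_new, L), t + dt_used)
    # quadrature consistent with the position update: the predictor-point
    # rate for full Heun steps; the start rate over a clamped sub-step
    q_end <- if (clamped) r$q else r_eu$q
    flux_int <- flux_int + dt_used * (r$q + q_end) / 2
    t <- t + dt_used
    x <- x_new
    if (crossed_boundary) {
      push_event(t, paste0("enter:", geom$id[geom_segment_index(geom, x)]))
    }
    rec(t, x, r_new$q, FALSE, flux_int)
    if (x >= L) push_event(t, "outlet_reached")
    if (err < pos_tol / 4) dt <- min(dt * 2, dt_max)
  }
  if (t < t_end && x >= L) {
    # trajectory ends at the outlet
  } else if (b_t[n_rec] < t_end) {
    rec(t_end, x, b_q[n_rec], b_s[n_rec], flux_int)
  }
  idx <- seq_len(n_rec)
  states <- tibble(
    time = b_t[idx],
    meniscus_position = b_x[idx],
    filled_volume = geom_cumvol(geom, b_x[idx]),
    flow_rate = b_q[idx],
    effective_viscosity = effective_viscosity(config$fluid, b_t[idx]),
    stopped = b_s[idx],
    flux_integral = b_f[idx]
  )
  structure(list(states = states,
                 events = tibble(time = ev_t, label = ev_lab),
                 config = config, x0 = max(x0, 1e-6)),
            class = "capilsep_trajectory")
}

#' @export
print.capilsep_trajectory <- function(x, ...) {
  st <- x$states
  cat("<capilsep_trajectory> ", nrow(st), " states, t in [0, ",
      format(max(st$time)), "] s, final position ",
      format(max(st$meniscus_position) * 1e3), " mm\n", sep = "")
  if (nrow(x$events)) {
    cat("  events:", paste(sprintf("%s@%.3gs", x$events$label, x$events$time),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

# volumetric rate through the fully primed chip (meniscus pinned at the
# outlet end; the collection tip sustains the outlet channel's capillary
# pull), used for the quasi-steady outflow phase of run_separation()
primed_rate <- function(geom, config, t) {
  out_seg <- config$segments[[geom$n]]
  pc <- capillary_pressure(out_seg, config$fluid)
  pg <- config$fluid$density * config$fluid$gravity *
    geom_height(geom, geom$total_length)
  mu <- effective_viscosity(config$fluid, t)
  res <- geom_resistance_unit_mu(geom, geom$total_length) * mu
  q <- max(0, (pc - pg) / res)
  pump <- ul_min_to_m3_s(config$operating$pump_rate_ul_min)
  if (pump > 0) min(q, pump) else q
}
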