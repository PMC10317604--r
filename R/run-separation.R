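#' Separated-plasma time series
#'
#' A validated tibble of (time, collected plasma volume) observations or
#' predictions: times strictly increasing, volumes non-negative and
#' non-decreasing.
#'
#' @param time_min Times in minutes, strictly increasing.
#' @param volume_ul Collected plasma volumes in microlitres.
#' @param source One of `"experiment"`, `"model"`, `"synthetic"`.
#' @return A `capilsep_series` tibble with columns `time_min`, `volume_ul`,
#'   `source`.
#' @export
separation_series <- function(time_min, volume_ul, source = "experiment") {
  source <- match.arg(source, c("experiment", "model", "synthetic"))
  if (length(time_min) != length(volume_ul)) {
    stop_validation("time and volume vectors must have equal length")
  }
  if (any(diff(time_min) <= 0)) {
    stop_validation("times must be strictly increasing")
  }
  if (any(volume_ul < 0)) stop_validation("volumes must be non-negative")
  if (any(diff(volume_ul) < -1e-9)) {
    stop_validation("collected volumes must be non-decreasing")
  }
  structure(tibble(time_min = time_min, volume_ul = volume_ul, source = source),
            class = c("capilsep_series", "tbl_df", "tbl", "data.frame"))
}

#' Simulate a full separation run
#'
#' Couples the capillary flow solver, the moving-mesh update, the
#' advection-diffusion transport step and the junction barrier into one
#' deterministic forward model. In `"primed"` mode the run starts from a
#' fully wetted device -- time zero is the instant separated liquid first
#' stands at the collection point -- and the quasi-steady outflow rate is
#' governed by the outlet capillary pull against the full-chip viscous
#' resistance with coagulation-grown viscosity. In `"dry"` mode the chip
#' fills from the regularised startup length first (Lucas-Washburn
#' dynamics, barrier stop/burst events) and switches to the primed outflow
#' once the meniscus reaches the outlet end. Collected plasma is the
#' cumulative plasma mass that has crossed the entry face of the outlet
#' segment, divided by the liquid density.
#'
#' @param config A `capilsep_chip`.
#' @param t_end Run duration in minutes.
#' @param n_cells Finite-volume cells for the transport grid.
#' @param dt_max Maximum time step in seconds.
#' @param start `"primed"` or `"dry"`.
#' @param feed `"open"` (inlet reservoir continuously supplies sample at the
#'   feed composition) or `"closed"` (no inflow; flow rate forced to zero).
#' @param snapshot_times Optional times (minutes) at which to store the
#'   concentration profile.
#' @return A `capilsep_separation` object: list with `trajectory`
#'   (`capilsep_trajectory`), `series` (`capilsep_series` of collected
#'   plasma), `snapshots` (named list of tibbles), `field` (final
#'   `capilsep_field`), `collected_by_species` (ul), `fed_volume_ul`, and
#'   the run settings.
#' @export
run_separation <- function(config, t_end = 12, n_cells = 200, dt_max = 0.1,
                           start = c("primed", "dry"),
                           feed = c("open", "closed"),
                           snapshot_times = NULL) {
  start <- match.arg(start)
  feed <- match.arg(feed)
  geom <- chip_geometry(config)
  rho <- config$fluid$density
  x_oe <- geom_outlet_entry(geom)
  x_j <- geom_junction_position(geom)
  t_end_s <- min_to_s(t_end)
  n_steps <- max(2L, ceiling(t_end_s / dt_max))
  dt <- t_end_s / n_steps

  fill_traj <- NULL
  if (start == "dry") {
    fill_traj <- advance_flow(config, t_end_s, dt_max = dt_max)
    st <- fill_traj$states
    xfun <- stats::approxfun(st$time, st$meniscus_position, rule = 2,
                             method = "linear", ties = "ordered")
    L_init <- max(st$meniscus_position[1], 1e-6)
  } else {
    L_init <- geom$total_length
  }

  field <- concentration_field(config, n_cells, length = L_init, feed = feed)
  if (is.finite(x_j) && !is.na(x_j)) {
    # pin the barrier to the interior face nearest the band entry on the
    # final (full-length) mesh; step_transport re-locates it while the
    # domain is still growing
    xf_full <- field$X_faces * geom$total_length
    j_face <- (2:n_cells)[which.min(abs(xf_full[2:n_cells] - x_j))]
    field <- apply_barrier(field, config$species, j_face - 1L)
    field$junction$position <- x_j
  }

  m0_up <- stats::setNames(
    vapply(field$species, function(s) mass_upstream(field, x_oe, s), numeric(1)),
    field$species)
  fed <- stats::setNames(numeric(length(field$species)), field$species)

  times_min <- numeric(n_steps)
  collected <- numeric(n_steps)
  q_rec <- numeric(n_steps)
  pos_rec <- numeric(n_steps)
  snapshots <- list()
  snap_left <- sort(unique(snapshot_times))

  t_now <- 0
  for (k in seq_len(n_steps)) {
    t_next <- k * dt
    if (start == "dry") {
      L0 <- max(xfun(t_now), L_init)
      L1 <- max(xfun(t_next), L0)
      if (L0 >= geom$total_length - 1e-12) {
        Qk <- primed_rate(geom, config, t_now + dt / 2)  # midpoint rule
        L1 <- geom$total_length
      } else {
        Qk <- (geom_cumvol(geom, L1) - geom_cumvol(geom, L0)) / dt
      }
    } else {
      L1 <- geom$total_length
      Qk <- primed_rate(geom, config, t_now + dt / 2)    # midpoint rule
    }
    if (feed == "closed") Qk <- 0
    field <- step_transport(field,
                            list(flow_rate = Qk, meniscus_position = L1),
                            dt, config)
    fed <- fed + attr(field, "inflow_mass")
    t_now <- t_next
    times_min[k] <- s_to_min(t_now)
    up_now <- mass_upstream(field, x_oe, "plasma")
    collected[k] <- m3_to_ul((m0_up[["plasma"]] + fed[["plasma"]] - up_now) / rho)
    q_rec[k] <- Qk
    pos_rec[k] <- L1
    while (length(snap_left) && times_min[k] >= snap_left[1] - 1e-9) {
      snapshots[[sprintf("t%gmin", snap_left[1])]] <- as_tibble(field)
      snap_left <- snap_left[-1]
    }
  }

  collected <- pmax(cummax(pmax(collected, 0)), 0)  # guard sub-nanoliter float noise
  series <- separation_series(times_min, collected, source = "model")
  collected_by_species <- vapply(field$species, function(s) {
    m3_to_ul((m0_up[[s]] + fed[[s]] - mass_upstream(field, x_oe, s)) / rho)
  }, numeric(1))

  traj <- if (!is.null(fill_traj)) fill_traj else {
    structure(list(
      states = tibble(
        time = c(0, min_to_s(times_min)),
        meniscus_position = c(geom$total_length, pos_rec),
        filled_volume = geom_cumvol(geom, c(geom$total_length, pos_rec)),
        flow_rate = c(q_rec[1], q_rec),
        effective_viscosity = effective_viscosity(config$fluid,
                                                  c(0, min_to_s(times_min))),
        stopped = c(q_rec[1], q_rec) <= 0,
        flux_integral = c(0, cumsum(q_rec * dt))
      ),
      events = tibble(time = numeric(0), label = character(0)),
      config = config, x0 = geom$total_length),
      class = "capilsep_trajectory")
  }

  structure(list(
    trajectory = traj,
    series = series,
    snapshots = snapshots,
    field = field,
    collected_by_species = collected_by_species,
    fed_volume_ul = m3_to_ul(sum(fed) / rho),
    config = config,
    settings = list(t_end = t_end, n_cells = n_cells, dt_max = dt_max,
                    start = start, feed = feed, dt = dt)
  ), class = "capilsep_separation")
}

#' @export
print.capilsep_separation <- function(x, ...) {
  s <- x$series
  cat("<capilsep_separation> ", x$settings$start, " start, ",
      nrow(s), " steps over ", format(max(s$time_min)), " min\n", sep = "")
  cat("  collected plasma:", format(round(max(s$volume_ul), 3)), "ul",
      " (cells:", format(signif(x$collected_by_species[["cells"]], 3)), "ul)\n")
  invisible(x)
}

# model collected volume interpolated to observation times (monotone
# piecewise-linear; extrapolation holds the end values)
interpolate_series <- function(result, times_min) {
  s <- result$series
  stats::approx(c(0, s$time_min), c(0, s$volume_ul), xout = times_min,
                method = "linear", rule = 2, ties = "ordered")$y
}
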