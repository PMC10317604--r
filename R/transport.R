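#' Concentration field on the moving filled domain
#'
#' The filled part of the chip is mapped onto a fixed reference grid of
#' `n_cells` uniform cells on \[0, 1\]; the mapping to physical arc length is
#' the uniform stretch `x(X, t) = X * length(t)` (the one-dimensional
#' reduction of the Laplace mesh equation with a pinned inlet and a
#' meniscus-following outlet). Each species is carried as a per-cell mass,
#' from which partial densities and mass fractions follow; cell volumes come
#' from the exact chip geometry, so cells spanning a change of cross-section
#' are handled exactly.
#'
#' @param config A `capilsep_chip`.
#' @param n_cells Number of finite-volume cells (>= 3).
#' @param length Physical length of the filled domain, metres; defaults to
#'   the full chip length (a fully primed device).
#' @param feed `"open"` (inlet supplies sample at the feed composition) or
#'   `"closed"`.
#' @return A `capilsep_field` object.
#' @export
concentration_field <- function(config, n_cells = 200,
                                length = NULL, feed = "open") {
  stopifnot(n_cells >= 3)
  geom <- chip_geometry(config)
  L <- length %||% geom$total_length
  if (L <= 0 || L > geom$total_length + 1e-12) {
    stop_domain("field length must lie in (0, total chip length]")
  }
  feed <- match.arg(feed, c("open", "closed"))
  nm <- species_names(config)
  omega0 <- vapply(config$species, `[[`, numeric(1), "initial_mass_fraction")
  Xf <- seq(0, 1, length.out = n_cells + 1)
  V <- diff(geom_cumvol(geom, Xf * L))
  mass <- outer(V * config$fluid$density, omega0)
  colnames(mass) <- nm
  structure(list(
    n_cells = as.integer(n_cells),
    X_faces = Xf,
    length = L,
    geom = geom,
    species = nm,
    D = stats::setNames(vapply(config$species, `[[`, numeric(1), "diffusivity"), nm),
    rho = config$fluid$density,
    mass = mass,
    feed = if (feed == "open") {
      stats::setNames(config$fluid$density * omega0, nm)
    } else NULL,
    junction = NULL,
    flux_j = NULL
  ), class = "capilsep_field")
}

field_volumes <- function(field, length = field$length) {
  diff(geom_cumvol(field$geom, field$X_faces * length))
}

#' Mass fractions of a field
#'
#' @param field A `capilsep_field`.
#' @return Numeric vector of per-cell plasma mass fractions.
#' @export
omega_plasma <- function(field) {
  tot <- rowSums(field$mass)
  w <- field$mass[, "plasma"] / tot
  w[tot <= 0] <- NA_real_
  w
}

#' @exportS3Method tibble::as_tibble
as_tibble.capilsep_field <- function(x, ...) {
  xf <- x$X_faces * x$length
  centers <- (xf[-1] + xf[-length(xf)]) / 2
  tot <- rowSums(x$mass)
  tibble(
    x_m = centers,
    volume_m3 = field_volumes(x),
    omega_plasma = ifelse(tot > 0, x$mass[, "plasma"] / tot, NA_real_),
    omega_cells = ifelse(tot > 0, 1 - x$mass[, "plasma"] / tot, NA_real_)
  )
}

#' @export
print.capilsep_field <- function(x, ...) {
  cat("<capilsep_field> ", x$n_cells, " cells on [0, ",
      format(x$length * 1e3), " mm], species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  if (!is.null(x$junction)) {
    cat("  barrier junction at x =", format(x$junction$position * 1e3), "mm\n")
  }
  invisible(x)
}

#' Move the mesh to a new domain length
#'
#' Applies the uniform stretch of the one-dimensional Laplace mesh equation
#' (pinned inlet, meniscus-following outlet): every node velocity is
#' proportional to its reference coordinate, so the interior node at
#' X = 0.5 moves at half the meniscus speed. Cell species masses are kept,
#' which makes the remap conservative by construction; partial densities
#' dilate with the cell volumes.
#'
#' @param field A `capilsep_field`.
#' @param new_length New physical domain length, metres (> 0).
#' @return The field on the stretched mesh.
#' @export
update_mesh <- function(field, new_length) {
  if (!is.numeric(new_length) || new_length <= 0) {
    stop_domain("new_length must be > 0")
  }
  if (new_length > field$geom$total_length + 1e-12) {
    stop_domain("new_length exceeds the chip length")
  }
  field$length <- new_length
  field
}

#' Attach the cell-retention barrier to a field
#'
#' Marks the hydrophobic junction: the advective and diffusive flux of every
#' species across the junction face is subsequently multiplied by that
#' species' `barrier_transmission` during [step_transport()]. Mass that does
#' not cross stays in the upstream cell, so retained material accumulates
#' against the barrier. Plasma has transmission 1.
#'
#' @param field A `capilsep_field`.
#' @param species List of [species_properties()] (supplies the transmission
#'   factors).
#' @param junction_index Index of the cell immediately upstream of the
#'   junction face (the barrier sits at the downstream face of this cell).
#' @return The field with the junction attached.
#' @export
apply_barrier <- function(field, species, junction_index) {
  junction_index <- as.integer(junction_index)
  if (junction_index < 1 || junction_index >= field$n_cells) {
    stop_domain("junction_index must address an interior face")
  }
  eps <- stats::setNames(
    vapply(species, `[[`, numeric(1), "barrier_transmission"),
    vapply(species, `[[`, character(1), "name"))
  field$junction <- list(
    position = field$X_faces[junction_index + 1] * field$length,
    eps = eps[field$species]
  )
  field
}

# tridiagonal (Thomas) solve: lower[i] c[i-1] + diag[i] c[i] + upper[i] c[i+1] = rhs[i]
thomas_solve <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    m <- diag[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Advance the species field by one transport step
#'
#' One implicit (backward-time) finite-volume step of the binary
#' advection-diffusion system on the moving domain: first-order upwind
#' advection, central diffusion, and the arbitrary Lagrangian-Eulerian flux
#' correction for the mesh motion, with face sweep volumes computed exactly
#' from the chip geometry (which makes uniform fields invariant under pure
#' mesh motion). The meniscus face carries zero relative flux and zero
#' diffusive flux; when the domain spans the whole chip the front face is an
#' outflow at the upwind composition. An open inlet supplies sample at the
#' feed composition through a ghost cell. The junction transmission factors
#' of [apply_barrier()] multiply both flux components at the face nearest
#' the junction position.
#'
#' @param field A `capilsep_field` (holds the pre-step mesh).
#' @param flow A list or one-row data frame with `flow_rate` (m^3/s) and
#'   `meniscus_position` (m) at the end of the step.
#' @param dt Step length, seconds (> 0).
#' @param config The `capilsep_chip`.
#' @return The advanced field; attributes `inflow_mass` and `outflow_mass`
#'   (named per-species vectors, kg) report the boundary exchange of the
#'   step for external bookkeeping.
#' @export
step_transport <- function(field, flow, dt, config) {
  if (dt <= 0) stop_domain("dt must be > 0")
  geom <- field$geom
  n <- field$n_cells
  L_old <- field$length
  L_new <- flow$meniscus_position[1]
  if (!is.finite(L_new) || L_new <= 0) stop_domain("invalid new domain length")
  if (L_new < L_old - 1e-12 && L_new < geom$total_length - 1e-12) {
    # shrinking domains are outside the model's scope (no drainage phase)
    stop_domain("domain length must be non-decreasing")
  }
  Q <- max(flow$flow_rate[1], 0)
  field <- update_mesh(field, L_new)

  cache <- field$mesh_cache
  if (!is.null(cache) && cache$L_old == L_old && cache$L_new == L_new) {
    xf_new <- cache$xf_new; cv_old <- cache$cv_old; cv_new <- cache$cv_new
    V_new <- cache$V_new; area_f <- cache$area_f; dxc <- cache$dxc
  } else {
    xf_old <- field$X_faces * L_old
    xf_new <- field$X_faces * L_new
    cv_old <- geom_cumvol(geom, xf_old)
    cv_new <- geom_cumvol(geom, xf_new)
    V_new <- diff(cv_new)
    area_f <- vapply(xf_new,
                     function(x) geom_area_at(geom, min(x, geom$total_length)),
                     numeric(1))
    centers <- (xf_new[-1] + xf_new[-(n + 1)]) / 2
    dxc <- diff(centers)
    field$mesh_cache <- list(L_old = L_old, L_new = L_new, xf_new = xf_new,
                             cv_old = cv_old, cv_new = cv_new, V_new = V_new,
                             area_f = area_f, dxc = dxc)
  }
  sweep <- (cv_new - cv_old) / dt          # (A * xdot) at each face, exact GCL
  pinned <- L_new >= geom$total_length - 1e-12

  # relative volumetric flux through each face (n + 1 faces)
  W <- Q - sweep
  W[1] <- Q                                 # inlet face: mesh pinned
  W[n + 1] <- if (pinned && abs(L_new - L_old) < 1e-15) Q else 0

  # face transmission factors (junction)
  Tfac <- matrix(1, n + 1, length(field$species),
                 dimnames = list(NULL, field$species))
  if (!is.null(field$junction) && field$junction$position < L_new) {
    interior <- 2:n
    j <- interior[which.min(abs(xf_new[interior] - field$junction$position))]
    Tfac[j, ] <- field$junction$eps
  }

  inflow <- stats::setNames(numeric(length(field$species)), field$species)
  outflow <- inflow
  flux_j <- matrix(0, n + 1, length(field$species),
                   dimnames = list(NULL, field$species))
  new_mass <- field$mass

  for (s in field$species) {
    Ds <- field$D[[s]]
    Ts <- Tfac[, s]
    m_old <- field$mass[, s]
    # interior faces f = 2..n sit between cells f-1 and f
    f_int <- 2:n
    Wf <- W[f_int] * Ts[f_int]
    dcoef <- Ts[f_int] * Ds * area_f[f_int] / dxc   # diffusive conductance
    up_pos <- pmax(Wf, 0)    # coefficient on upstream (left) cell
    up_neg <- pmin(Wf, 0)    # coefficient on downstream (right) cell
    lower <- numeric(n); diag <- V_new / dt; upper <- numeric(n)
    rhs <- m_old / dt
    # face f contributes +F to cell f-1 (out) and -F to cell f (in)
    # F = up_pos*c[f-1] + up_neg*c[f] - dcoef*(c[f] - c[f-1])
    diag[f_int - 1] <- diag[f_int - 1] + up_pos + dcoef
    upper[f_int - 1] <- upper[f_int - 1] + up_neg - dcoef
    lower[f_int] <- lower[f_int] - up_pos - dcoef
    diag[f_int] <- diag[f_int] - up_neg + dcoef
    # inlet face: inflow at feed composition (known, goes to rhs)
    if (W[1] > 0) {
      if (is.null(field$feed)) {
        stop_domain("positive inflow with a closed inlet")
      }
      rhs[1] <- rhs[1] + W[1] * field$feed[[s]]
    }
    # front face: outflow at upwind composition when pinned
    if (W[n + 1] > 0) diag[n] <- diag[n] + W[n + 1]
    conc <- thomas_solve(lower, diag, upper, rhs)
    if (any(conc < -1e-9 * max(field$rho, 1))) {
      abort("negative concentration from the transport scheme",
            class = c("capilsep_integration_error", "capilsep_error"))
    }
    conc[conc < 0] <- 0
    new_mass[, s] <- V_new * conc
    if (W[1] > 0) inflow[[s]] <- dt * W[1] * field$feed[[s]]
    if (W[n + 1] > 0) outflow[[s]] <- dt * W[n + 1] * conc[n]
    flux_j[f_int, s] <- -dcoef * (conc[f_int] - conc[f_int - 1])
  }
  field$mass <- new_mass
  field$flux_j <- flux_j
  attr(field, "inflow_mass") <- inflow
  attr(field, "outflow_mass") <- outflow
  field
}

# plasma (or any species) mass in the part of the domain upstream of
# position x_cut, splitting the containing cell by exact volume fraction
mass_upstream <- function(field, x_cut, species = "plasma") {
  xf <- field$X_faces * field$length
  if (x_cut >= field$length) return(sum(field$mass[, species]))
  if (x_cut <= 0) return(0)
  cv <- geom_cumvol(field$geom, xf)
  V <- diff(cv)
  i <- findInterval(x_cut, xf, rightmost.closed = TRUE)
  i <- max(1L, min(field$n_cells, i))
  full <- if (i > 1) sum(field$mass[seq_len(i - 1), species]) else 0
  frac <- (geom_cumvol(field$geom, x_cut) - cv[i]) / V[i]
  full + frac * field$mass[i, species]
}
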