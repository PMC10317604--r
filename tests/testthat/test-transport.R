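test_that("a uniform field at zero flow is a fixed point of the step", {
  cfg <- tube_chip(D = 1e-9)
  f <- concentration_field(cfg, n_cells = 40, feed = "closed")
  f2 <- step_transport(f, list(flow_rate = 0, meniscus_position = f$length),
                       dt = 5, config = cfg)
  expect_equal(f2$mass, f$mass, tolerance = 1e-14)
})

test_that("pure advection moves a composition front at the flow speed", {
  cfg <- tube_chip(D = 0)
  n <- 100
  f <- concentration_field(cfg, n_cells = n, feed = "open")
  # step profile: pure plasma in the left third, feed composition beyond
  V <- capilsep:::field_volumes(f)
  rho <- f$rho
  third <- floor(n / 3)
  f$mass[seq_len(third), "plasma"] <- V[seq_len(third)] * rho
  f$mass[seq_len(third), "cells"] <- 0
  f$feed <- c(plasma = rho, cells = 0)      # keep feeding pure plasma
  A <- 1e-6                                  # 1 mm x 1 mm tube
  u <- 2e-4                                  # m/s
  Q <- u * A
  dt <- 0.25                                 # CFL = u dt / dx = 0.5
  n_steps <- 80
  for (k in seq_len(n_steps)) {
    f <- step_transport(f, list(flow_rate = Q, meniscus_position = f$length),
                        dt, cfg)
  }
  w <- omega_plasma(f)
  centers <- as_tibble(f)$x_m
  # front = first crossing of the midpoint composition
  w_mid <- (1 + cfg$species[[1]]$initial_mass_fraction) / 2
  i_front <- which(w < w_mid)[1]
  x_front_num <- centers[i_front]
  x_front_exact <- centers[third] + u * dt * n_steps
  dx <- f$length / n
  expect_lt(abs(x_front_num - x_front_exact), dx + 1e-12)
})

test_that("pure diffusion grows the second moment as 2 D t", {
  cfg <- tube_chip(D = 1e-8)
  n <- 120
  f <- concentration_field(cfg, n_cells = n, feed = "closed")
  # near-delta plasma pulse in the middle over a zero background
  f$mass[, "plasma"] <- 0
  V <- capilsep:::field_volumes(f)
  f$mass[n / 2, "plasma"] <- V[n / 2] * f$rho
  centers <- as_tibble(f)$x_m
  m2 <- function(ff) {
    m <- ff$mass[, "plasma"]
    mu <- sum(m * centers) / sum(m)
    sum(m * (centers - mu)^2) / sum(m)
  }
  m2_0 <- m2(f)
  t_tot <- 100
  dt <- 0.5
  for (k in seq_len(t_tot / dt)) {
    f <- step_transport(f, list(flow_rate = 0, meniscus_position = f$length),
                        dt, cfg)
  }
  D <- 1e-8
  growth <- m2(f) - m2_0
  expect_lt(abs(growth - 2 * D * t_tot) / (2 * D * t_tot), 0.02)
  # mass unchanged (closed domain)
  expect_equal(sum(f$mass[, "plasma"]), V[n / 2] * f$rho, tolerance = 1e-12)
})

test_that("the mesh stretch is the linear Laplace solution and conserves mass", {
  cfg <- tube_chip()
  f <- concentration_field(cfg, n_cells = 50, length = 4e-3)
  f_same <- update_mesh(f, 4e-3)
  expect_identical(f_same$length, 4e-3)
  expect_equal(f_same$mass, f$mass)
  f2 <- update_mesh(f, 8e-3)
  # node at X = 0.5 moved by half the meniscus displacement
  expect_equal(f2$X_faces[26] * f2$length - f$X_faces[26] * 4e-3,
               (8e-3 - 4e-3) * f$X_faces[26])
  expect_equal(sum(f2$mass), sum(f$mass), tolerance = 1e-10)
  expect_true(all(diff(f2$X_faces * f2$length) > 0))   # no tangling
  expect_error(update_mesh(f, -1), class = "capilsep_domain_error")
})

test_that("growing the domain with the meniscus preserves a uniform field", {
  cfg <- tube_chip(D = 0)
  f <- concentration_field(cfg, n_cells = 40, length = 2e-3, feed = "open")
  A <- 1e-6
  u <- 1e-4
  w0 <- omega_plasma(f)[1]
  for (k in 1:50) {
    L_new <- f$length + u * 0.5
    f <- step_transport(f, list(flow_rate = u * A, meniscus_position = L_new),
                        0.5, cfg)
  }
  expect_equal(omega_plasma(f), rep(w0, 40), tolerance = 1e-12)
  # the swept volume entered through the inlet: total mass matches exactly
  geomv <- capilsep:::geom_cumvol(f$geom, f$length)
  expect_equal(sum(f$mass), geomv * f$rho, tolerance = 1e-9)
})

test_that("the junction transmits species fluxes in proportion to epsilon", {
  # steady flux balance across the junction: the cell against the barrier
  # is the well-mixed upstream compartment the transmitted flux samples, so
  # the downstream/upstream concentration ratio tends to eps (in = eps W c,
  # out = W c_downstream)
  cfg <- tube_chip(D = 0, eps_cells = 0.0098)
  n <- 60
  f <- concentration_field(cfg, n_cells = n, feed = "open")
  f <- apply_barrier(f, cfg$species, 30)
  V <- capilsep:::field_volumes(f)
  A <- 1e-6; u <- 5e-4
  for (k in seq_len(600)) {
    f <- step_transport(f, list(flow_rate = u * A,
                                meniscus_position = f$length), 0.2, cfg)
  }
  c_cake <- f$mass[30, "cells"] / V[30]
  c_dn <- f$mass[31, "cells"] / V[31]
  expect_equal(unname(c_dn / c_cake), 0.0098, tolerance = 0.01)

  # the retained mass piles up against the barrier (far above the feed)
  expect_gt(c_cake, 2 * (f$mass[29, "cells"] / V[29]))

  # eps = 0: a clean downstream stays clean forever
  cfg0 <- tube_chip(D = 1e-10, eps_cells = 0)
  f0 <- concentration_field(cfg0, n_cells = 60, feed = "open")
  f0$mass[31:60, "cells"] <- 0
  f0 <- apply_barrier(f0, cfg0$species, 30)
  for (k in 1:100) {
    f0 <- step_transport(f0, list(flow_rate = 5e-10,
                                  meniscus_position = f0$length), 0.2, cfg0)
  }
  expect_equal(sum(f0$mass[31:60, "cells"]), 0)

  # eps = 1 is identical to no barrier at all
  cfg1 <- tube_chip(D = 1e-10, eps_cells = 1)
  fa <- concentration_field(cfg1, n_cells = 60, feed = "open")
  fb <- apply_barrier(fa, cfg1$species, 30)
  for (k in 1:50) {
    flow <- list(flow_rate = 5e-10, meniscus_position = fa$length)
    fa <- step_transport(fa, flow, 0.2, cfg1)
    fb <- step_transport(fb, flow, 0.2, cfg1)
  }
  expect_equal(fa$mass, fb$mass, tolerance = 1e-14)
})

test_that("collected cell mass decreases with barrier strength", {
  collected_cells <- function(eps) {
    cfg <- default_chip(eps_cells = eps)
    res <- run_separation(cfg, t_end = 4, n_cells = fast$n_cells,
                          dt_max = fast$dt_max)
    res$collected_by_species[["cells"]]
  }
  v <- vapply(c(0, 0.25, 0.5, 1), collected_cells, numeric(1))
  expect_true(all(diff(v) >= -1e-9))   # non-decreasing in transmission
})

test_that("omega respects the discrete maximum principle", {
  cfg <- tube_chip(D = 5e-10)
  n <- 60
  f <- concentration_field(cfg, n_cells = n, feed = "open")
  # non-uniform start: plasma-rich left, plasma-poor right; feed = left value
  V <- capilsep:::field_volumes(f)
  w_hi <- 0.8; w_lo <- 0.3
  f$mass[1:30, "plasma"] <- V[1:30] * f$rho * w_hi
  f$mass[1:30, "cells"] <- V[1:30] * f$rho * (1 - w_hi)
  f$mass[31:60, "plasma"] <- V[31:60] * f$rho * w_lo
  f$mass[31:60, "cells"] <- V[31:60] * f$rho * (1 - w_lo)
  f$feed <- c(plasma = f$rho * w_hi, cells = f$rho * (1 - w_hi))
  for (k in 1:200) {
    f <- step_transport(f, list(flow_rate = 4e-10,
                                meniscus_position = f$length), 0.5, cfg)
    w <- omega_plasma(f)
    expect_true(all(w >= w_lo - 1e-12 & w <= w_hi + 1e-12))
  }
})

test_that("plasma mass is conserved to 1e-8 with a closed inlet", {
  # non-uniform field, diffusion and barrier active, no inflow
  cfg <- tube_chip(D = 1e-9, eps_cells = 0.0098)
  f <- concentration_field(cfg, n_cells = 80, feed = "closed")
  V <- capilsep:::field_volumes(f)
  f$mass[1:40, "plasma"] <- V[1:40] * f$rho * 0.9
  f$mass[1:40, "cells"] <- V[1:40] * f$rho * 0.1
  f <- apply_barrier(f, cfg$species, 40)
  m0 <- colSums(f$mass)
  for (k in 1:200) {
    f <- step_transport(f, list(flow_rate = 0, meniscus_position = f$length),
                        1, cfg)
  }
  m1 <- colSums(f$mass)
  expect_lt(abs(m1[["plasma"]] - m0[["plasma"]]) / m0[["plasma"]], 1e-8)
  expect_lt(abs(m1[["cells"]] - m0[["cells"]]) / m0[["cells"]], 1e-8)

  # and through the coupled driver with the inlet closed
  res <- run_separation(default_chip(D_f = 1e-9), t_end = 5, n_cells = 60,
                        dt_max = 1, feed = "closed")
  f0 <- concentration_field(default_chip(D_f = 1e-9), n_cells = 60)
  expect_lt(abs(sum(res$field$mass[, "plasma"]) - sum(f0$mass[, "plasma"])) /
              sum(f0$mass[, "plasma"]), 1e-8)
})

test_that("collected volume is grid-converged to 1% and non-decreasing", {
  v1 <- run_separation(default_chip(), t_end = 6, n_cells = 60, dt_max = 1)
  v2 <- run_separation(default_chip(), t_end = 6, n_cells = 120, dt_max = 1)
  c1 <- max(v1$series$volume_ul)
  c2 <- max(v2$series$volume_ul)
  expect_lt(abs(c1 - c2) / c2, 0.01)
  expect_true(all(diff(v1$series$volume_ul) >= 0))
})

test_that("with pure plasma feed the collected volume is the filled outlet volume", {
  cfg <- chip_config(
    segments = default_chip()$segments,
    fluid = fluid_properties(coagulation_tau = Inf),
    species = plasma_only_species(),
    operating = operating_conditions(pump_rate_ul_min = 0.8, hematocrit = 0))
  # stop while the front is still inside the outlet segment
  res <- run_separation(cfg, t_end = 2.4, n_cells = 80, dt_max = 1,
                        start = "dry")
  geom <- capilsep:::chip_geometry(cfg)
  x_oe <- capilsep:::geom_outlet_entry(geom)
  L_fin <- res$field$length
  expect_gt(L_fin, x_oe)   # front has entered the outlet by t_end
  v_outlet <- m3_to_ul(capilsep:::geom_cumvol(geom, L_fin) -
                       capilsep:::geom_cumvol(geom, x_oe))
  expect_equal(max(res$series$volume_ul), v_outlet, tolerance = 1e-6)
})
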