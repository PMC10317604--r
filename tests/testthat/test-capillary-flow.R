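test_that("entry pressures follow Young-Laplace in both geometries", {
  fl <- fluid_properties(surface_tension = 0.05, coagulation_tau = Inf)
  s_cyl <- segment("c", "vertical_well", 1e-3, cyl_section(0.5e-3), 60, 90)
  expect_equal(capillary_pressure(s_cyl, fl), 100)  # 2*0.05*cos60 / 5e-4
  # theta = 90 gives zero whatever the geometry
  expect_equal(capillary_pressure(
    segment("n", "horizontal_channel", 1e-3,
            rect_section(1e-3, 1e-4), 90), fl), 0, tolerance = 1e-12)
  # a square channel pulls exactly twice as hard as a parallel-plate gap d
  d <- 1e-4
  sq <- segment("sq", "horizontal_channel", 1e-3, rect_section(d, d), 40)
  expect_equal(capillary_pressure(sq, fl),
               2 * (2 * fl$surface_tension * cos(40 * pi / 180) / d))
  # non-wetting segment opposes
  s_ph <- segment("p", "vertical_well", 1e-3, cyl_section(0.5e-3), 110, 90)
  expect_lt(capillary_pressure(s_ph, fl), 0)
})

test_that("hydraulic resistance matches Poiseuille hand values and is linear", {
  fl <- fluid_properties(coagulation_tau = Inf)
  s <- segment("c", "vertical_well", 2e-3, cyl_section(1e-3), 40, 90)
  # 8 mu L / (pi R^4) with mu = 1 mPa s, L = 1 mm, R = 1 mm
  expect_equal(hydraulic_resistance(s, 1e-3, 1e-3),
               8e-6 / (pi * 1e-12), tolerance = 1e-12)
  expect_equal(hydraulic_resistance(s, 0, 1e-3), 0)
  expect_equal(hydraulic_resistance(s, 1e-3, 2e-3),
               2 * hydraulic_resistance(s, 1e-3, 1e-3))
  expect_equal(hydraulic_resistance(s, 2e-3, 1e-3),
               2 * hydraulic_resistance(s, 1e-3, 1e-3))
  expect_error(hydraulic_resistance(s, -1e-4, 1e-3),
               class = "capilsep_domain_error")
  # rectangular formula is symmetric under swapping width and depth
  r1 <- segment("r", "horizontal_channel", 1e-3, rect_section(1e-3, 2e-4), 40)
  r2 <- segment("r", "horizontal_channel", 1e-3, rect_section(2e-4, 1e-3), 40)
  expect_equal(hydraulic_resistance(r1, 1e-3, 1e-3),
               hydraulic_resistance(r2, 1e-3, 1e-3))
})

test_that("coagulation grows the effective viscosity exponentially", {
  fl <- fluid_properties(viscosity = 2e-3, coagulation_tau = 100)
  expect_equal(effective_viscosity(fl, 0), 2e-3)
  expect_equal(effective_viscosity(fl, 100), 2e-3 * exp(1))
  fl_inf <- fluid_properties(viscosity = 2e-3, coagulation_tau = Inf)
  expect_equal(effective_viscosity(fl_inf, 1e6), 2e-3)
  expect_error(effective_viscosity(fl, -1), class = "capilsep_domain_error")
})

test_that("driving pressure combines capillarity and hydrostatics", {
  # all horizontal, theta = 90, no pump: exactly zero
  cfg0 <- washburn_chip(theta = 90)
  expect_equal(driving_pressure(cfg0, flow_state(cfg0, 0, 5e-3)), 0,
               tolerance = 1e-12)
  # vertical wetting capillary filled to height h: gravity term is rho g h
  cfg <- chip_config(
    segments = list(segment("v", "vertical_well", 50e-3,
                            cyl_section(0.25e-3), 90, 90)),
    fluid = fluid_properties(coagulation_tau = Inf),
    species = plasma_only_species(),
    operating = operating_conditions(pump_rate_ul_min = 0, hematocrit = 0))
  h <- 10e-3
  expect_equal(driving_pressure(cfg, flow_state(cfg, 0, h)),
               -cfg$fluid$density * cfg$fluid$gravity * h)
  # hydrophobic band entry with the reference chip: negative (stop)
  ref <- default_chip()
  x_band <- 7e-3 + 1e-9   # inlet 5 mm + lower well 2 mm
  expect_lt(driving_pressure(ref, flow_state(ref, 0, x_band)), 0)
  expect_error(driving_pressure(ref, flow_state(ref, 0, 1)),
               class = "capilsep_domain_error")
})

test_that("numeric filling matches the closed-form Washburn law within 1%", {
  cfg <- washburn_chip(depth = 200e-6, theta = 60, mu = 0.35, length = 10e-3)
  sg <- cfg$segments[[1]]
  k <- cfg$fluid$surface_tension * cos(60 * pi / 180) *
    sg$cross_section$depth / (3 * cfg$fluid$viscosity)
  x_half <- sg$length / 2
  t_half <- x_half^2 / k               # x(t) = sqrt(k t)
  traj <- advance_flow(cfg, t_end = t_half, dt_max = t_half / 400)
  x_num <- utils::tail(traj$states$meniscus_position, 1)
  expect_lt(abs(x_num - x_half) / x_half, 0.01)
})

test_that("volume bookkeeping agrees with the flux integral", {
  traj <- advance_flow(default_chip(), t_end = 240, dt_max = 0.5)
  st <- traj$states
  dv <- st$filled_volume - st$filled_volume[1]
  err <- abs(dv[nrow(st)] - st$flux_integral[nrow(st)]) / dv[nrow(st)]
  expect_lt(err, 1e-6)
  # monotonicity of position and volume, non-negative rates
  expect_true(all(diff(st$meniscus_position) >= 0))
  expect_true(all(diff(st$filled_volume) >= -1e-18))
  expect_true(all(st$flow_rate >= 0))
})

test_that("halving the step changes the final position by under 0.1%", {
  cfg <- washburn_chip()
  t_end <- 2
  a <- advance_flow(cfg, t_end, dt_max = 0.02)
  b <- advance_flow(cfg, t_end, dt_max = 0.01)
  xa <- utils::tail(a$states$meniscus_position, 1)
  xb <- utils::tail(b$states$meniscus_position, 1)
  expect_lt(abs(xa - xb) / xb, 1e-3)
})

test_that("a vertical capillary approaches the Jurin height monotonically", {
  cfg <- chip_config(
    segments = list(segment("v", "vertical_well", 50e-3,
                            cyl_section(0.25e-3), 40, 90)),
    fluid = fluid_properties(viscosity = 5e-3, coagulation_tau = Inf),
    species = plasma_only_species(),
    operating = operating_conditions(pump_rate_ul_min = 0, hematocrit = 0))
  h_jurin <- 2 * cfg$fluid$surface_tension * cos(40 * pi / 180) /
    (cfg$fluid$density * cfg$fluid$gravity * 0.25e-3)
  traj <- advance_flow(cfg, t_end = 400, dt_max = 0.5)
  st <- traj$states
  expect_true(all(diff(st$meniscus_position) >= 0))
  x_fin <- utils::tail(st$meniscus_position, 1)
  expect_lt(x_fin, h_jurin)
  expect_gt(x_fin, 0.9 * h_jurin)
  expect_lt(utils::tail(st$flow_rate, 1),
            0.02 * max(st$flow_rate))
})

test_that("theta = 90 everywhere means the meniscus never advances", {
  cfg <- washburn_chip(theta = 90)
  traj <- advance_flow(cfg, t_end = 5, dt_max = 0.1)
  expect_equal(utils::tail(traj$states$meniscus_position, 1), traj$x0)
  expect_true(utils::tail(traj$states$stopped, 1))
})

test_that("the hydrophobic band stops passive flow and the pump bursts it", {
  # passive chip: permanent stop at the band entry
  passive <- default_chip()
  passive$operating$pump_rate_ul_min <- 0
  tr_p <- advance_flow(passive, t_end = 600, dt_max = 0.5)
  expect_true(any(grepl("^stop:band", tr_p$events$label)))
  expect_false(any(grepl("^burst:", tr_p$events$label)))
  expect_true(utils::tail(tr_p$states$stopped, 1))
  expect_equal(utils::tail(tr_p$states$meniscus_position, 1), 7e-3,
               tolerance = 1e-6)
  # metered chip: stop followed by an immediate burst, then outlet reached
  tr <- advance_flow(default_chip(), t_end = 1800, dt_max = 0.5)
  expect_true(any(grepl("^stop:band", tr$events$label)))
  expect_true(any(grepl("^burst:band", tr$events$label)))
  i_stop <- which(grepl("^stop:band", tr$events$label))[1]
  i_burst <- which(grepl("^burst:band", tr$events$label))[1]
  expect_gt(i_burst, i_stop)
  expect_gt(utils::tail(tr$states$meniscus_position, 1), 8e-3)
})
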