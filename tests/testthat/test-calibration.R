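test_that("calibration_spec validates parameters, bounds and starts", {
  expect_error(calibration_spec(free = "nonsense"),
               class = "capilsep_validation_error")
  expect_error(calibration_spec(free = "tau_c", lower = c(tau_c = 1000),
                                upper = c(tau_c = 500)),
               class = "capilsep_validation_error")
  expect_error(calibration_spec(free = "tau_c", init = c(tau_c = 1)),
               class = "capilsep_validation_error")
  sp <- calibration_spec(free = c("tau_c", "D_f"))
  expect_identical(sp$params$name, c("tau_c", "D_f"))
})

test_that("the optimiser never returns a worse objective than the start", {
  truth <- list(tau_c = 600)
  obs <- generate_series(synthetic_spec(ground_truth = truth,
                                        volume_noise_sd = 0, seed = 3),
                         n_cells = fast$n_cells, dt_max = fast$dt_max)
  cal <- calibrate(default_chip(), obs,
                   calibration_spec(free = c("tau_c", "D_f"),
                                    n_cells = fast$n_cells,
                                    dt_max = fast$dt_max, max_evals = 60))
  expect_lte(cal$objective, cal$initial_objective)
  expect_s3_class(tidy(cal), "tbl_df")
  expect_named(glance(cal),
               c("r_squared", "mse", "n_obs", "n_evals", "converged"))
})

test_that("single-parameter search matches a two-stage grid oracle", {
  truth <- list(tau_c = 500)
  obs <- generate_series(synthetic_spec(ground_truth = truth,
                                        volume_noise_sd = 0, seed = 1),
                         n_cells = 40, dt_max = 4)
  cfg <- default_chip()
  objective <- function(tau) {
    res <- run_separation(capilsep:::set_params(cfg, c(tau_c = tau)),
                          t_end = max(obs$time_min), n_cells = 40, dt_max = 4)
    mse(obs$volume_ul, capilsep:::interpolate_series(res, obs$time_min))
  }
  # independent brute-force oracle: coarse log grid, then a fine local grid
  g1 <- exp(seq(log(120), log(7200), length.out = 80))
  f1 <- vapply(g1, objective, numeric(1))
  i1 <- which.min(f1)
  lo <- g1[max(1, i1 - 1)]; hi <- g1[min(length(g1), i1 + 1)]
  g2 <- seq(lo, hi, length.out = 120)
  f2 <- vapply(g2, objective, numeric(1))
  tau_grid <- g2[which.min(f2)]
  cell <- diff(g2)[1]

  cal <- calibrate(cfg, obs,
                   calibration_spec(free = "tau_c", n_cells = 40, dt_max = 4))
  expect_lt(abs(cal$par[["tau_c"]] - tau_grid), cell + 1e-9)
})

test_that("noiseless synthetic data recover the generating parameters within 5%", {
  truth <- c(tau_c = 700, theta_philic = 48)
  cfg_truth <- capilsep:::set_params(default_chip(), truth)
  res <- run_separation(cfg_truth, t_end = 12, n_cells = fast$n_cells,
                        dt_max = fast$dt_max)
  obs <- separation_series(c(2, 4, 6, 8, 10, 12),
                           capilsep:::interpolate_series(res, c(2, 4, 6, 8, 10, 12)),
                           source = "synthetic")
  cal <- calibrate(default_chip(), obs,
                   calibration_spec(free = c("tau_c", "theta_philic"),
                                    n_cells = fast$n_cells,
                                    dt_max = fast$dt_max, max_evals = 250,
                                    reltol = 1e-10))
  expect_lt(abs(cal$par[["tau_c"]] - truth[["tau_c"]]) / truth[["tau_c"]], 0.05)
  expect_lt(abs(cal$par[["theta_philic"]] - truth[["theta_philic"]]) /
              truth[["theta_philic"]], 0.05)
  expect_gte(cal$fit$r_squared, 0.999)
})

test_that("completion extrapolation inverts the saturating model analytically", {
  # a slow-coagulation configuration whose collected-volume curve is the
  # closed form a * tau * (1 - exp(-t/tau)) in the primed regime
  tau <- 1800
  cfg <- default_chip(coagulation_tau = tau)
  cal <- calibrate(cfg, generate_series(synthetic_spec(
    ground_truth = list(tau_c = tau), volume_noise_sd = 0, seed = 2),
    n_cells = 80, dt_max = 1),
    calibration_spec(free = "tau_c", n_cells = 80, dt_max = 1))
  expect_equal(cal$par[["tau_c"]], tau, tolerance = 0.01)

  geom <- capilsep:::chip_geometry(cfg)
  q0 <- capilsep:::primed_rate(geom, default_chip(coagulation_tau = Inf), 0)
  w0 <- cfg$species[[1]]$initial_mass_fraction
  a_ul_min <- m3_s_to_ul_min(q0) * w0          # initial collection rate
  available <- 10 * 0.6                        # rounded-HCT plasma content
  tau_min <- cal$par[["tau_c"]] / 60
  closed_form <- function(f) {
    -tau_min * log(1 - f * available / (a_ul_min * tau_min))
  }
  dt_min <- 1 / 60
  for (f in c(0.3, 0.5, 0.63)) {
    t_num <- extrapolate_completion(cfg, cal, f, cap_min = 120,
                                    n_cells = 80, dt_max = 1)
    expect_lt(abs(t_num - closed_form(f)), 2 * dt_min)
  }
  expect_equal(as.numeric(extrapolate_completion(cfg, cal, 0)), 0)
  # monotone non-decreasing in the completion fraction
  tt <- extrapolate_completion(cfg, cal, c(0.2, 0.4, 0.6, 0.8),
                               cap_min = 240, n_cells = 80, dt_max = 1)
  expect_true(all(diff(tt) > 0))
})

test_that("an unattainable completion yields the explicit sentinel", {
  # coagulation freezes the flow long before the target volume
  tau <- 150
  cfg <- default_chip(coagulation_tau = tau)
  obs <- generate_series(synthetic_spec(ground_truth = list(tau_c = tau),
                                        volume_noise_sd = 0, seed = 5),
                         n_cells = fast$n_cells, dt_max = fast$dt_max)
  cal <- calibrate(cfg, obs, calibration_spec(free = "tau_c",
                                              n_cells = fast$n_cells,
                                              dt_max = fast$dt_max))
  out <- extrapolate_completion(cfg, cal, 0.999, cap_min = 60,
                                n_cells = fast$n_cells, dt_max = fast$dt_max)
  expect_true(is.na(out))
  expect_identical(attr(out, "reason"), "not attained")
  expect_true(is.finite(attr(out, "final_volume_ul")))
})
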