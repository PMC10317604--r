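# evaluate code with a temporary RNG state, restoring the caller's
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic dataset
#'
#' Defines the ground truth and the noise model used to emulate the two
#' experimental tables the analysis consumes: a saturating recovery curve
#' with additive truncated-Gaussian volume noise, and per-analyte cell
#' counts Poisson-sampled on a counted aliquot. One integer seed controls
#' all randomness and is embedded in every output.
#'
#' @param ground_truth Named list of model parameters (any subset understood
#'   by [calibration_spec()]), the generating truth for the forward model.
#' @param observation_times Sampling times in minutes.
#' @param volume_noise_sd Additive measurement noise SD on volumes, ul
#'   (Gaussian truncated at zero).
#' @param count_means Named vector of true input concentrations per ul.
#' @param true_transmission Named vector of true barrier transmissions per
#'   analyte (fraction reaching the output).
#' @param aliquot_volume_ul Counted aliquot volume, ul (> 0).
#' @param seed Integer seed.
#' @return A `capilsep_synthspec` object.
#' @export
synthetic_spec <- function(ground_truth = list(tau_c = 900, D_f = 1e-10),
                           observation_times = c(3, 7, 9, 12),
                           volume_noise_sd = 0.1,
                           count_means = c(WBC = 7110, RBC = 4.42e6),
                           true_transmission = c(WBC = 0.0098, RBC = 0.0098),
                           aliquot_volume_ul = 1,
                           seed = 1L) {
  if (volume_noise_sd < 0) stop_validation("volume_noise_sd must be >= 0")
  if (aliquot_volume_ul <= 0) stop_validation("aliquot_volume_ul must be > 0")
  if (!all(names(true_transmission) %in% names(count_means))) {
    stop_validation("true_transmission names must match count_means")
  }
  if (any(true_transmission < 0 | true_transmission > 1)) {
    stop_validation("transmissions must lie in [0, 1]")
  }
  structure(list(ground_truth = ground_truth,
                 observation_times = observation_times,
                 volume_noise_sd = volume_noise_sd,
                 count_means = count_means,
                 true_transmission = true_transmission,
                 aliquot_volume_ul = aliquot_volume_ul,
                 seed = as.integer(seed)),
            class = "capilsep_synthspec")
}

# one draw per element of `mean`, truncated below at zero via inverse CDF
rtruncnorm0 <- function(mean, sd) {
  if (sd == 0) return(mean)
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(length(mean), lo, 1), mean, sd)
}

#' Generate a synthetic separation series
#'
#' Runs the forward model at the ground-truth parameters, samples the
#' collected volume at the observation times, adds truncated-Gaussian
#' noise, and restores monotonicity by isotonic (least-squares monotone)
#' projection. With zero noise the output equals the noiseless forward
#' model exactly. Reproducible given the seed.
#'
#' @param spec A [synthetic_spec()].
#' @param config Base chip configuration (defaults to [default_chip()]).
#' @param n_cells,dt_max Simulation resolution of the forward model.
#' @param model Optional precomputed [run_separation()] result at the
#'   ground truth, to amortise the forward run over many noise replicates.
#' @return A `capilsep_series` with `source = "synthetic"`; attributes
#'   `seed` and `spec_hash` identify the generating spec.
#' @export
generate_series <- function(spec, config = default_chip(),
                            n_cells = 120, dt_max = 1, model = NULL) {
  stopifnot(inherits(spec, "capilsep_synthspec"))
  res <- model %||% run_separation(
    set_params(config, spec$ground_truth),
    t_end = max(spec$observation_times),
    n_cells = n_cells, dt_max = dt_max, start = "primed")
  v_true <- interpolate_series(res, spec$observation_times)
  v_obs <- with_seed(spec$seed, rtruncnorm0(v_true, spec$volume_noise_sd))
  if (spec$volume_noise_sd > 0) {
    v_obs <- stats::isoreg(spec$observation_times, v_obs)$yf
  }
  out <- separation_series(spec$observation_times, pmax(v_obs, 0),
                           source = "synthetic")
  attr(out, "seed") <- spec$seed
  attr(out, "spec_hash") <- rlang::hash(unclass(spec))
  out
}

#' Generate a synthetic cell-count table
#'
#' Input counts are Poisson-sampled around the true concentration on the
#' counted aliquot; output counts around the true concentration attenuated
#' by the per-analyte transmission. Reproducible given the seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with `analyte`, `input_value`, `output_value`
#'   (concentrations per ul); attributes `seed` and `spec_hash`.
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "capilsep_synthspec"))
  a <- spec$aliquot_volume_ul
  analytes <- names(spec$count_means)
  tab <- with_seed(spec$seed + 1L, {
    input <- stats::rpois(length(analytes), spec$count_means * a) / a
    eps <- spec$true_transmission[analytes]
    output <- stats::rpois(length(analytes), spec$count_means * eps * a) / a
    tibble(analyte = analytes, input_value = input, output_value = output)
  })
  attr(tab, "seed") <- spec$seed
  attr(tab, "spec_hash") <- rlang::hash(unclass(spec))
  tab
}
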