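#' Read and write separation series CSV files
#'
#' The schema is a UTF-8, comma-delimited file with mandatory header
#' `time_min,volume_ul`. Reading validates the series invariants (strictly
#' increasing times, non-negative non-decreasing volumes) and reports the
#' offending row on failure; write-then-read is the identity.
#'
#' @param path CSV file path.
#' @param source Source label attached on read.
#' @return [read_series()] returns a `capilsep_series`; [write_series()]
#'   returns `path` invisibly.
#' @export
read_series <- function(path, source = "experiment") {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "volume_ul") %in% names(df))) {
    stop_schema("series CSV must have header columns time_min, volume_ul")
  }
  if (nrow(df) == 0) stop_schema("series CSV has no data rows")
  if (any(!is.finite(df$time_min)) || any(!is.finite(df$volume_ul))) {
    bad <- which(!is.finite(df$time_min) | !is.finite(df$volume_ul))[1]
    stop_schema(sprintf("malformed value in series row %d", bad))
  }
  bad_t <- which(diff(df$time_min) <= 0)
  if (length(bad_t)) {
    stop_schema(sprintf("times not strictly increasing at row %d", bad_t[1] + 1))
  }
  bad_v <- which(diff(df$volume_ul) < -1e-9)
  if (length(bad_v)) {
    stop_schema(sprintf("volumes decrease at row %d", bad_v[1] + 1))
  }
  if (any(df$volume_ul < 0)) {
    stop_schema(sprintf("negative volume at row %d", which(df$volume_ul < 0)[1]))
  }
  separation_series(df$time_min, df$volume_ul, source = source)
}

#' @param series A data frame with `time_min` and `volume_ul`.
#' @rdname read_series
#' @export
write_series <- function(series, path) {
  utils::write.csv(series[, c("time_min", "volume_ul")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write cell-count tables
#'
#' Schema: header `analyte,input_value,output_value`; values are
#' concentrations in the units the counter prints (per-ul counts for WBC
#' and RBC). Analytes must be unique and values non-negative.
#'
#' @param path CSV file path.
#' @return [read_counts()] returns a tibble; [write_counts()] returns
#'   `path` invisibly.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("analyte", "input_value", "output_value") %in% names(df))) {
    stop_schema("count CSV must have header analyte, input_value, output_value")
  }
  if (anyDuplicated(df$analyte)) {
    stop_schema(sprintf("duplicate analyte '%s'", df$analyte[duplicated(df$analyte)][1]))
  }
  if (any(df$input_value < 0 | df$output_value < 0)) {
    stop_schema("count values must be non-negative")
  }
  as_tibble(df)
}

#' @param counts A data frame with `analyte`, `input_value`, `output_value`.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(counts[, c("analyte", "input_value", "output_value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a flow trajectory as CSV
#'
#' Columns: `time_s`, `position_m`, `volume_ul`, `flow_rate_ul_min`,
#' `stopped`.
#'
#' @param trajectory A `capilsep_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  st <- trajectory$states
  utils::write.csv(
    data.frame(time_s = st$time, position_m = st$meniscus_position,
               volume_ul = m3_to_ul(st$filled_volume),
               flow_rate_ul_min = m3_s_to_ul_min(st$flow_rate),
               stopped = st$stopped),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled reference measurements
#'
#' The two measured tables of the study device that ship with the package:
#' the separated-plasma volume series (collected volume at 3, 7, 9 and
#' 12 minutes) and the pre/post cell-counter readings (WBC, RBC, HGB, HCT).
#'
#' @return A `capilsep_series`, respectively a count tibble.
#' @export
measured_separation_series <- function() {
  read_series(system.file("extdata", "plasma_volume_series.csv",
                          package = "capilsep", mustWork = TRUE))
}

#' @rdname measured_separation_series
#' @export
measured_cell_counts <- function() {
  read_counts(system.file("extdata", "cell_counts.csv",
                          package = "capilsep", mustWork = TRUE))
}

sorted_deep <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, sorted_deep)
  } else x
}

write_report_json <- function(x, path) {
  jsonlite::write_json(sorted_deep(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

run_manifest <- function(subcommand, config, input_paths = character(0),
                        seed = NULL) {
  hashes <- if (length(input_paths)) {
    as.list(tools::md5sum(input_paths))
  } else list()
  list(
    subcommand = subcommand,
    config_hash = rlang::hash(config_to_list(config)),
    input_hashes = hashes,
    seed = seed,
    tool_version = as.character(utils::packageVersion("capilsep")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

#' Reproduce the study's headline analysis
#'
#' Runs the full replication pipeline against the bundled measurement
#' tables: build the reference chip, fit the cell transmission analytically
#' from the red-cell counts, calibrate the coagulation time constant and
#' effective diffusivity to the volume series, evaluate purity, recovery,
#' goodness of fit, and the extrapolated time to 99.9% separation, and
#' write `summary.json` plus a `manifest.json` into `output_dir`. JSON keys
#' are sorted and numbers written at full precision, so identical inputs
#' give byte-identical summaries.
#'
#' @param output_dir Directory to create/write into.
#' @param hct_mode Hematocrit convention for recovery and completion
#'   (default `"rounded"`, the device's headline convention).
#' @param spec Calibration specification.
#' @return The run manifest (list), invisibly, with the summary attached as
#'   attribute `summary`.
#' @export
replicate_paper <- function(output_dir, hct_mode = "rounded",
                            spec = calibration_spec()) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("replication stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = c("capilsep_stage_error", "capilsep_error"))
    })
  }
  obs <- stage("load-series", measured_separation_series())
  counts <- stage("load-counts", measured_cell_counts())

  purity <- stage("purity", purity_by_analyte(counts))
  rbc <- counts[counts$analyte == "RBC", ]
  eps_rbc <- rbc$output_value / rbc$input_value

  config <- default_chip(eps_cells = eps_rbc)
  op <- config$operating
  recovery <- stage("recovery", recovery_fraction(
    max(obs$volume_ul), op$injected_volume_ul, op$hematocrit,
    hct_mode = hct_mode, quiet = TRUE))

  cal <- stage("calibrate", calibrate(config, obs, spec))
  completion <- stage("extrapolate",
                      extrapolate_completion(config, cal, 0.999,
                                             hct_mode = hct_mode,
                                             n_cells = spec$n_cells,
                                             dt_max = spec$dt_max))
  cal$extrapolated_completion_time <- completion

  summary <- list(
    purity_by_analyte = stats::setNames(as.list(purity$purity_pct),
                                        purity$analyte),
    purity_rbc_pct_rounded = round_half_away(
      purity$purity_pct[purity$analyte == "RBC"], 0),
    recovery_pct = recovery,
    recovery_pct_rounded = round_half_away(recovery, 1),
    r_squared = cal$fit$r_squared,
    mse = cal$fit$mse,
    completion_time_99_9 = if (is.na(completion)) NA else completion,
    calibrated_parameters = as.list(cal$par),
    hct_mode = hct_mode
  )
  fixture_paths <- c(
    system.file("extdata", "plasma_volume_series.csv", package = "capilsep"),
    system.file("extdata", "cell_counts.csv", package = "capilsep"))
  manifest <- run_manifest("replicate-paper", config, fixture_paths)
  write_report_json(summary, file.path(output_dir, "summary.json"))
  write_report_json(manifest, file.path(output_dir, "manifest.json"))
  attr(manifest, "summary") <- summary
  attr(manifest, "calibration") <- cal
  invisible(manifest)
}
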