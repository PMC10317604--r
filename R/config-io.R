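#' Read and write chip configuration files
#'
#' Configurations are stored as JSON or YAML with four top-level blocks:
#' `segments` (array, each with `id`, `kind`, `length`, `cross_section`
#' (`shape` + dimensions in metres), `contact_angle`, `inclination`,
#' `wettability_zone`), `fluid`, `species` and `operating`. Geometry and
#' fluid values are SI; operating values carry their units in the field
#' names (`injected_volume_ul`, `pump_rate_ul_min`, `run_duration_min`).
#' Omitted optional fields take the documented defaults and each
#' substitution is logged once via `message()`. `coagulation_tau` may be the
#' string `"Inf"` (JSON has no infinity literal).
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return [load_config()] returns a validated `capilsep_chip`;
#'   [write_config()] returns `path` invisibly.
#' @examples
#' cfg <- default_chip()
#' f <- tempfile(fileext = ".json")
#' write_config(cfg, f)
#' cfg2 <- load_config(f)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("config file not found: %s", path))
  raw <- parse_config_file(path)
  config_from_list(raw)
}

parse_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop_schema(sprintf("unsupported config extension '.%s' (use .json or .yaml)", ext))
  }
}

need_field <- function(lst, field, where) {
  if (is.null(lst[[field]])) {
    stop_schema(sprintf("missing required field '%s' in %s", field, where))
  }
  lst[[field]]
}

opt_field <- function(lst, field, default, where) {
  if (is.null(lst[[field]])) {
    message(sprintf("config: %s.%s not given, using default %s",
                    where, field, format(default)))
    default
  } else {
    lst[[field]]
  }
}

as_tau <- function(x) {
  if (is.character(x)) x <- suppressWarnings(as.numeric(sub("^Inf$", "Inf", x)))
  if (is.null(x) || is.na(x)) Inf else x
}

config_from_list <- function(raw) {
  segs_raw <- need_field(raw, "segments", "config")
  segs <- lapply(seq_along(segs_raw), function(i) {
    s <- segs_raw[[i]]
    where <- sprintf("segments[%d]", i)
    cs <- need_field(s, "cross_section", where)
    shape <- need_field(cs, "shape", paste0(where, ".cross_section"))
    section <- switch(shape,
      rectangular = rect_section(need_field(cs, "width", where),
                                 need_field(cs, "depth", where)),
      cylindrical = cyl_section(need_field(cs, "radius", where)),
      stop_schema(sprintf("%s: unknown cross-section shape '%s'", where, shape))
    )
    segment(
      id = need_field(s, "id", where),
      kind = need_field(s, "kind", where),
      length = need_field(s, "length", where),
      cross_section = section,
      contact_angle = need_field(s, "contact_angle", where),
      inclination = opt_field(s, "inclination", 0, where),
      wettability_zone = opt_field(s, "wettability_zone", "native", where)
    )
  })
  fl <- raw$fluid %||% list()
  fluid <- fluid_properties(
    viscosity = opt_field(fl, "viscosity", 3.5e-3, "fluid"),
    density = opt_field(fl, "density", 1060, "fluid"),
    surface_tension = opt_field(fl, "surface_tension", 0.058, "fluid"),
    gravity = opt_field(fl, "gravity", 9.81, "fluid"),
    coagulation_tau = as_tau(opt_field(fl, "coagulation_tau", Inf, "fluid"))
  )
  op <- raw$operating %||% list()
  operating <- operating_conditions(
    injected_volume_ul = opt_field(op, "injected_volume_ul", 10, "operating"),
    pump_rate_ul_min = opt_field(op, "pump_rate_ul_min", 0.8, "operating"),
    hematocrit = opt_field(op, "hematocrit", 0.399, "operating"),
    run_duration_min = opt_field(op, "run_duration_min", 12, "operating")
  )
  species <- if (is.null(raw$species)) {
    message("config: species not given, using binary plasma/cells defaults")
    NULL
  } else {
    lapply(seq_along(raw$species), function(i) {
      sp <- raw$species[[i]]
      where <- sprintf("species[%d]", i)
      species_properties(
        name = need_field(sp, "name", where),
        diffusivity = need_field(sp, "diffusivity", where),
        molecular_weight = opt_field(sp, "molecular_weight", 1, where),
        initial_mass_fraction = need_field(sp, "initial_mass_fraction", where),
        barrier_transmission = opt_field(sp, "barrier_transmission", 1, where)
      )
    })
  }
  chip_config(segments = segs, fluid = fluid, species = species,
              operating = operating)
}

config_to_list <- function(config) {
  list(
    segments = lapply(config$segments, function(s) {
      cs <- s$cross_section
      list(id = s$id, kind = s$kind, length = s$length,
           cross_section = unclass(cs),
           contact_angle = s$contact_angle, inclination = s$inclination,
           wettability_zone = s$wettability_zone)
    }),
    fluid = {
      f <- unclass(config$fluid)
      if (is.infinite(f$coagulation_tau)) f$coagulation_tau <- "Inf"
      f
    },
    species = lapply(config$species, unclass),
    operating = unclass(config$operating)
  )
}

#' @param config A `capilsep_chip` to serialise.
#' @rdname load_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "capilsep_chip"))
  lst <- config_to_list(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
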