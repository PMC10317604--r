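#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

stop_validation <- function(msg, ...) {
  abort(msg, class = c("capilsep_validation_error", "capilsep_error"), ...)
}
stop_schema <- function(msg, ...) {
  abort(msg, class = c("capilsep_schema_error", "capilsep_error"), ...)
}
stop_domain <- function(msg, ...) {
  abort(msg, class = c("capilsep_domain_error", "capilsep_error"), ...)
}

#' Channel cross-sections
#'
#' A flow segment is either a rectangular channel (width `w`, depth `d`) or a
#' cylindrical bore (radius `r`). All dimensions are in metres.
#'
#' @param width,depth,radius Cross-section dimensions in metres, all > 0.
#' @return A cross-section object used by [segment()].
#' @export
rect_section <- function(width, depth) {
  if (!is.numeric(width) || width <= 0 || !is.numeric(depth) || depth <= 0) {
    stop_validation("rectangular cross-section requires width > 0 and depth > 0")
  }
  structure(list(shape = "rectangular", width = width, depth = depth),
            class = "capilsep_section")
}

#' @rdname rect_section
#' @export
cyl_section <- function(radius) {
  if (!is.numeric(radius) || radius <= 0) {
    stop_validation("cylindrical cross-section requires radius > 0")
  }
  structure(list(shape = "cylindrical", radius = radius),
            class = "capilsep_section")
}

section_area <- function(cs) {
  switch(cs$shape,
    rectangular = cs$width * cs$depth,
    cylindrical = pi * cs$radius^2
  )
}

#' Define one flow segment of the chip
#'
#' The device is an ordered chain of segments from inlet to outlet. Each
#' segment has a single wettability (effective advancing contact angle) and a
#' fixed inclination; vertical upward flow is +90 degrees.
#'
#' @param id Character label, unique within a chip.
#' @param kind One of `"horizontal_channel"`, `"vertical_well"`,
#'   `"outlet_channel"`.
#' @param length Segment length along the flow path, metres (> 0).
#' @param cross_section A [rect_section()] or [cyl_section()].
#' @param contact_angle Effective advancing contact angle in degrees,
#'   strictly between 0 and 180.
#' @param inclination Degrees from horizontal in \[-90, 90\]; +90 means the
#'   liquid rises vertically while traversing the segment.
#' @param wettability_zone One of `"hydrophilic_coated"`, `"hydrophobic_band"`,
#'   `"native"`.
#' @return A `capilsep_segment` object.
#' @export
segment <- function(id, kind, length, cross_section, contact_angle,
                    inclination = 0, wettability_zone = "native") {
  kind <- match.arg(kind, c("horizontal_channel", "vertical_well", "outlet_channel"))
  wettability_zone <- match.arg(
    wettability_zone, c("hydrophilic_coated", "hydrophobic_band", "native"))
  if (!inherits(cross_section, "capilsep_section")) {
    stop_validation(sprintf("segment '%s': cross_section must be rect_section() or cyl_section()", id))
  }
  if (!is.numeric(length) || length <= 0) {
    stop_validation(sprintf("segment '%s': length must be > 0", id))
  }
  if (!is.numeric(contact_angle) || contact_angle <= 0 || contact_angle >= 180) {
    stop_validation(sprintf("segment '%s': contact_angle must lie strictly between 0 and 180 degrees", id))
  }
  if (!is.numeric(inclination) || inclination < -90 || inclination > 90) {
    stop_validation(sprintf("segment '%s': inclination must lie in [-90, 90] degrees", id))
  }
  structure(
    list(id = as.character(id), kind = kind, length = length,
         cross_section = cross_section, contact_angle = contact_angle,
         inclination = inclination, wettability_zone = wettability_zone),
    class = "capilsep_segment"
  )
}

#' Fluid properties of the sample
#'
#' Whole-blood bulk properties are treated as constant along the chip except
#' for the effective viscosity, which grows exponentially with the
#' coagulation time constant `coagulation_tau` (seconds; `Inf` disables the
#' slowdown). Defaults are literature values for whole blood at ambient
#' temperature, not measurements of a specific sample, and are meant to be
#' overridden or calibrated.
#'
#' @param viscosity Effective dynamic viscosity \eqn{\mu_l}, Pa s. The
#'   default (0.35 Pa s) is the low-shear apparent viscosity of coagulating
#'   whole blood in the creeping-flow regime of a passive chip (shear rates
#'   well below 1/s), not the familiar high-shear value of a few mPa s; see
#'   the methods vignette.
#' @param density Density \eqn{\rho_l}, kg/m^3.
#' @param surface_tension Surface tension \eqn{\sigma}, N/m.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param coagulation_tau Time constant of exponential viscosity growth,
#'   seconds; `Inf` disables coagulation.
#' @return A `capilsep_fluid` object.
#' @export
fluid_properties <- function(viscosity = 0.35, density = 1060,
                             surface_tension = 0.058, gravity = 9.81,
                             coagulation_tau = Inf) {
  vals <- c(viscosity = viscosity, density = density,
            surface_tension = surface_tension, gravity = gravity)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_validation("fluid properties must all be finite and strictly positive")
  }
  if (!(is.numeric(coagulation_tau) && (coagulation_tau > 0))) {
    stop_validation("coagulation_tau must be > 0 (Inf disables coagulation)")
  }
  structure(list(viscosity = viscosity, density = density,
                 surface_tension = surface_tension, gravity = gravity,
                 coagulation_tau = coagulation_tau),
            class = "capilsep_fluid")
}

#' Species carried by the flow
#'
#' The binary mixture reduction tracks two species, `"plasma"` and `"cells"`,
#' as mass fractions. Cells are modelled as a dissolved species whose flux
#' across the hydrophobic junction is attenuated by the barrier transmission
#' factor `barrier_transmission` (1 = passes freely, 0 = fully retained).
#'
#' @param name `"plasma"` or `"cells"` (free labels are allowed but the chip
#'   validator requires exactly one `"plasma"`).
#' @param diffusivity Effective Fickian diffusivity \eqn{D^f}, m^2/s (>= 0).
#' @param molecular_weight Nominal molecular weight, kg/mol; retained for
#'   completeness of the property set, it cancels identically in the binary
#'   reduction and never enters the solver.
#' @param initial_mass_fraction Mass fraction \eqn{\omega} in the feed, in
#'   \[0, 1\].
#' @param barrier_transmission Fraction of the species flux transmitted across
#'   the hydrophobic junction, in \[0, 1\].
#' @return A `capilsep_species` object.
#' @export
species_properties <- function(name, diffusivity, molecular_weight = 1,
                               initial_mass_fraction,
                               barrier_transmission = 1) {
  if (!is.numeric(diffusivity) || diffusivity < 0) {
    stop_validation(sprintf("species '%s': diffusivity must be >= 0", name))
  }
  if (initial_mass_fraction < 0 || initial_mass_fraction > 1) {
    stop_validation(sprintf("species '%s': initial_mass_fraction must lie in [0, 1]", name))
  }
  if (barrier_transmission < 0 || barrier_transmission > 1) {
    stop_validation(sprintf("species '%s': barrier_transmission must lie in [0, 1]", name))
  }
  structure(list(name = as.character(name), diffusivity = diffusivity,
                 molecular_weight = molecular_weight,
                 initial_mass_fraction = initial_mass_fraction,
                 barrier_transmission = barrier_transmission),
            class = "capilsep_species")
}

#' Operating conditions of a separation run
#'
#' @param injected_volume_ul Sample volume loaded at the inlet, microlitres.
#' @param pump_rate_ul_min Metering rate of the loading pump, microlitres per
#'   minute; 0 means purely passive operation.
#' @param hematocrit Red-cell volume fraction of the sample, in \[0, 1).
#' @param run_duration_min Nominal duration of the experiment, minutes.
#' @return A `capilsep_operating` object.
#' @export
operating_conditions <- function(injected_volume_ul = 10,
                                 pump_rate_ul_min = 0.8,
                                 hematocrit = 0.399,
                                 run_duration_min = 12) {
  if (injected_volume_ul <= 0) stop_validation("injected_volume_ul must be > 0")
  if (pump_rate_ul_min < 0) stop_validation("pump_rate_ul_min must be >= 0")
  if (hematocrit < 0 || hematocrit >= 1) stop_validation("hematocrit must lie in [0, 1)")
  if (run_duration_min <= 0) stop_validation("run_duration_min must be > 0")
  structure(list(injected_volume_ul = injected_volume_ul,
                 pump_rate_ul_min = pump_rate_ul_min,
                 hematocrit = hematocrit,
                 run_duration_min = run_duration_min),
            class = "capilsep_operating")
}

#' Assemble a chip configuration
#'
#' Validates the segment chain (non-empty, unique ids), the species set
#' (exactly one `"plasma"`, mass fractions summing to 1 within 1e-12 after a
#' tiny renormalisation), and bundles fluid and operating conditions.
#'
#' @param segments List of [segment()]s ordered inlet to outlet.
#' @param fluid A [fluid_properties()] object.
#' @param species List of [species_properties()] objects.
#' @param operating An [operating_conditions()] object.
#' @return A `capilsep_chip` object.
#' @export
chip_config <- function(segments, fluid = fluid_properties(),
                        species = NULL, operating = operating_conditions()) {
  if (length(segments) == 0) stop_validation("segments must be non-empty")
  if (!all(vapply(segments, inherits, logical(1), "capilsep_segment"))) {
    stop_validation("all segments must be built with segment()")
  }
  ids <- vapply(segments, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_validation(sprintf("duplicate segment id '%s'", ids[duplicated(ids)][1]))
  }
  if (is.null(species)) {
    species <- default_species(operating$hematocrit)
  }
  nm <- vapply(species, `[[`, character(1), "name")
  if (sum(nm == "plasma") != 1) {
    stop_validation("species must contain exactly one entry named 'plasma'")
  }
  w <- vapply(species, `[[`, numeric(1), "initial_mass_fraction")
  if (abs(sum(w) - 1) > 1e-6) {
    stop_validation(sprintf("species mass fractions sum to %.8f, expected 1", sum(w)))
  }
  w <- w / sum(w)  # remove floating drift; sums to 1 within 1e-12
  for (i in seq_along(species)) species[[i]]$initial_mass_fraction <- w[i]
  structure(list(segments = segments, fluid = fluid, species = species,
                 operating = operating),
            class = "capilsep_chip")
}

default_species <- function(hematocrit, D_f = 1e-10, eps_cells = 0.0098) {
  list(
    species_properties("plasma", diffusivity = D_f,
                       initial_mass_fraction = 1 - hematocrit,
                       barrier_transmission = 1),
    species_properties("cells", diffusivity = D_f,
                       initial_mass_fraction = hematocrit,
                       barrier_transmission = eps_cells)
  )
}

#' The reference chip
#'
#' Returns the configuration of the study device: a horizontal inlet channel
#' (180 um deep), a vertical cylindrical well of 4 mm total height whose top
#' 1 mm is an uncoated hydrophobic band, and a horizontal outlet channel
#' (100 um deep). Channel depths, the well height, the band length, the
#' injected volume (10 ul), the pump metering rate (0.8 ul/min) and the
#' sample hematocrit (0.399) are the device's stated values. Planar widths,
#' channel lengths and the well bore are not stated; they are fixed here at
#' fabrication-typical values chosen so that the filled chip's nominal
#' hydraulic conductance reproduces the measured early-time collection rate
#' (see the methods vignette). Contact angles (40 deg on surfactant-coated
#' zones, 110 deg on the hydrophobic band, 100 deg native) and the fluid
#' properties are literature-based defaults and calibration starting points.
#'
#' @param hematocrit Sample hematocrit, default 0.399.
#' @param coagulation_tau Initial coagulation time constant, seconds
#'   (default 900 s; refined by [calibrate()]).
#' @param D_f Effective diffusivity of both species, m^2/s (default 1e-10;
#'   refined by [calibrate()]).
#' @param eps_cells Barrier transmission of cells (default 0.0098).
#' @return A `capilsep_chip` object with 5 segments.
#' @export
default_chip <- function(hematocrit = 0.399, coagulation_tau = 900,
                         D_f = 1e-10, eps_cells = 0.0098) {
  segs <- list(
    segment("inlet", "horizontal_channel", length = 5e-3,
            cross_section = rect_section(width = 1e-3, depth = 180e-6),
            contact_angle = 40, inclination = 0,
            wettability_zone = "hydrophilic_coated"),
    segment("well_lower", "vertical_well", length = 2e-3,
            cross_section = cyl_section(radius = 0.25e-3),
            contact_angle = 40, inclination = 90,
            wettability_zone = "hydrophilic_coated"),
    segment("band", "vertical_well", length = 1e-3,
            cross_section = cyl_section(radius = 0.25e-3),
            contact_angle = 110, inclination = 90,
            wettability_zone = "hydrophobic_band"),
    segment("well_upper", "vertical_well", length = 1e-3,
            cross_section = cyl_section(radius = 0.25e-3),
            contact_angle = 40, inclination = 90,
            wettability_zone = "hydrophilic_coated"),
    segment("outlet", "outlet_channel", length = 8.5e-3,
            cross_section = rect_section(width = 0.5e-3, depth = 100e-6),
            contact_angle = 40, inclination = 0,
            wettability_zone = "hydrophilic_coated")
  )
  chip_config(
    segments = segs,
    fluid = fluid_properties(coagulation_tau = coagulation_tau),
    species = default_species(hematocrit, D_f = D_f, eps_cells = eps_cells),
    operating = operating_conditions(hematocrit = hematocrit)
  )
}

#' @export
print.capilsep_chip <- function(x, ...) {
  cat("<capilsep_chip> ", length(x$segments), " segments, total length ",
      format(sum(vapply(x$segments, `[[`, numeric(1), "length")) * 1e3),
      " mm, volume ", format(round(m3_to_ul(chip_total_volume(x)), 3)),
      " ul\n", sep = "")
  cat("  species:", paste(vapply(x$species, `[[`, character(1), "name"),
                          collapse = ", "), "\n")
  cat("  hematocrit:", x$operating$hematocrit,
      " injected:", x$operating$injected_volume_ul, "ul\n")
  invisible(x)
}

chip_total_volume <- function(config) {
  sum(vapply(config$segments, function(s) s$length * section_area(s$cross_section),
             numeric(1)))
}

species_names <- function(config) {
  vapply(config$species, `[[`, character(1), "name")
}

get_species <- function(config, name) {
  config$species[[match(name, species_names(config))]]
}
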