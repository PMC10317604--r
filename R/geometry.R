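# Internal arc-length geometry of the segment chain.
#
# The chip is parameterised by arc length x from the inlet (x = 0) to the
# outlet end (x = L_total). All quantities below are exact piecewise-constant
# or piecewise-linear functions of x.

chip_geometry <- function(config) {
  segs <- config$segments
  len <- vapply(segs, `[[`, numeric(1), "length")
  area <- vapply(segs, function(s) section_area(s$cross_section), numeric(1))
  sin_incl <- sin(vapply(segs, `[[`, numeric(1), "inclination") * pi / 180)
  x1 <- cumsum(len)
  x0 <- c(0, x1[-length(x1)])
  zone <- vapply(segs, `[[`, character(1), "wettability_zone")
  list(
    config = config,
    n = length(segs),
    id = vapply(segs, `[[`, character(1), "id"),
    length = len, area = area, sin_incl = sin_incl,
    x0 = x0, x1 = x1, total_length = x1[length(x1)],
    cum_vol = c(0, cumsum(len * area)),
    cum_h = c(0, cumsum(len * sin_incl)),
    zone = zone,
    segments = segs
  )
}

# index of the segment containing position x; at an interior boundary the
# *next* segment is returned (entry conditions apply there)
geom_segment_index <- function(geom, x, entering = TRUE) {
  if (x < 0 || x > geom$total_length + 1e-12) {
    stop_domain(sprintf("position %g m lies outside the segment chain [0, %g]",
                        x, geom$total_length))
  }
  i <- findInterval(x, geom$x0, rightmost.closed = FALSE)
  if (!entering) i <- findInterval(x, geom$x0, left.open = TRUE)
  max(1L, min(geom$n, i))
}

# filled volume between 0 and x (m^3), vectorised
geom_cumvol <- function(geom, x) {
  vapply(x, function(xi) {
    filled <- pmin(pmax(xi - geom$x0, 0), geom$length)
    sum(filled * geom$area)
  }, numeric(1))
}

# vertical rise of the filled path [0, x] (m)
geom_height <- function(geom, x) {
  filled <- pmin(pmax(x - geom$x0, 0), geom$length)
  sum(filled * geom$sin_incl)
}

# cross-section area at position x (uses the segment being entered at
# boundaries so velocities refer to the segment ahead of the meniscus)
geom_area_at <- function(geom, x) {
  geom$area[geom_segment_index(geom, min(x, geom$total_length))]
}

# total viscous resistance of the wetted path [0, x] at unit viscosity;
# multiply by mu to get Pa s/m^3
geom_resistance_unit_mu <- function(geom, x) {
  filled <- pmin(pmax(x - geom$x0, 0), geom$length)
  sum(vapply(seq_len(geom$n), function(i) {
    if (filled[i] <= 0) return(0)
    hydraulic_resistance(geom$segments[[i]], filled[i], 1)
  }, numeric(1)))
}

# arc position of the entry face of the outlet (last) segment
geom_outlet_entry <- function(geom) geom$x0[geom$n]

# arc position of the entry face of the hydrophobic band (NA if absent)
geom_junction_position <- function(geom) {
  i <- which(geom$zone == "hydrophobic_band")
  if (length(i) == 0) return(NA_real_)
  geom$x0[i[1]]
}
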