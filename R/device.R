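#' Transducer array displacement map
#'
#' Describes the diced PZT array driving the chamber floor: a rows x cols
#' grid of square units embedded in epoxy, each region vibrating with a
#' (real, in-phase) normal displacement amplitude proportional to the drive
#' voltage.
#'
#' Unit regions are labelled like chess coordinates: rows `A`, `B`, `C`, ...
#' and columns `1`, `2`, `3`, ... so the centre unit of a 3 x 3 array is
#' `"B2"`. The array is centred on the chamber origin.
#'
#' @param units Numeric matrix (rows x cols) of displacement-per-volt for
#'   each unit, in m/V. All values must be >= 0.
#' @param epoxy Displacement-per-volt of the epoxy kerf between and around
#'   units, m/V.
#' @param unit_size Side length of each square unit, m.
#' @param pitch Centre-to-centre unit spacing, m. Must be >= `unit_size`.
#' @param drive_voltage Drive amplitude in V (>= 0).
#' @param frequency Drive frequency in Hz (> 0).
#'
#' @return An object of class `al_transducer_map`.
#' @export
transducer_map <- function(units, epoxy, unit_size = 2e-3, pitch = 2.4e-3,
                           drive_voltage = 60, frequency = 660e3) {
  units <- as.matrix(units)
  if (any(!is.finite(units)) || any(units < 0))
    stop("'units' displacement-per-volt values must all be finite and >= 0")
  check_nonnegative_scalar(epoxy, "epoxy")
  check_positive_scalar(unit_size, "unit_size")
  check_positive_scalar(pitch, "pitch")
  if (unit_size > pitch) stop("'unit_size' must not exceed 'pitch'")
  check_nonnegative_scalar(drive_voltage, "drive_voltage")
  check_positive_scalar(frequency, "frequency")
  structure(
    list(units = units, epoxy = epoxy, unit_size = unit_size, pitch = pitch,
         drive_voltage = drive_voltage, frequency = frequency),
    class = "al_transducer_map")
}

#' @export
print.al_transducer_map <- function(x, ...) {
  cat(sprintf("<al_transducer_map> %d x %d units of %g mm at %g mm pitch, %g V, %g kHz\n",
              nrow(x$units), ncol(x$units), x$unit_size * 1e3, x$pitch * 1e3,
              x$drive_voltage, x$frequency / 1e3))
  cat("  units (nm/V):\n")
  print(round(x$units * 1e9, 3))
  cat(sprintf("  epoxy (nm/V): %g\n", x$epoxy * 1e9))
  invisible(x)
}

# Cartesian centres (m) of each unit; array centred on the origin.
unit_centers <- function(map) {
  nr <- nrow(map$units); nc <- ncol(map$units)
  cx <- (seq_len(nr) - (nr + 1) / 2) * map$pitch
  cy <- (seq_len(nc) - (nc + 1) / 2) * map$pitch
  list(x = cx, y = cy)
}

# Lateral extent (m) of the diced block: units plus surrounding kerf.
array_footprint <- function(map) {
  nr <- max(nrow(map$units), ncol(map$units))
  (nr - 1) * map$pitch + map$unit_size + (map$pitch - map$unit_size)
}

#' Chamber configuration
#'
#' Rectangular fluid chamber above the transducer array: lateral walls and
#' lid are modelled as (locally reacting) impedance boundaries, the floor is
#' displacement-driven. `Inf` impedances mean acoustically rigid walls.
#'
#' @param lateral_size Length-2 numeric `(Lx, Ly)`, m.
#' @param fluid_height Fluid column height h, m.
#' @param fluid An `al_material`; defaults to [water()].
#' @param top_impedance Lid impedance, Pa s/m (glass lid ~ 13e6).
#' @param side_impedance Side-wall impedance, Pa s/m (aluminium frame ~ 17e6).
#' @param symmetry Logical length-2 `(x, y)`: whether the configuration is
#'   mirror-symmetric about the x = 0 and y = 0 planes, enabling the
#'   quarter-domain solve.
#'
#' @return An object of class `al_chamber`.
#' @export
chamber_config <- function(lateral_size = c(10e-3, 10e-3),
                           fluid_height = 1.1e-3,
                           fluid = water(),
                           top_impedance = 13e6,
                           side_impedance = 17e6,
                           symmetry = c(TRUE, TRUE)) {
  stopifnot(length(lateral_size) == 2, all(lateral_size > 0))
  check_positive_scalar(fluid_height, "fluid_height")
  if (!inherits(fluid, "al_material")) stop("'fluid' must be an al_material")
  if (!(top_impedance > 0)) stop("'top_impedance' must be > 0 (use Inf for rigid)")
  if (!(side_impedance > 0)) stop("'side_impedance' must be > 0 (use Inf for rigid)")
  structure(
    list(lateral_size = lateral_size, fluid_height = fluid_height,
         fluid = fluid, top_impedance = top_impedance,
         side_impedance = side_impedance,
         symmetry = as.logical(symmetry)),
    class = "al_chamber")
}

#' @export
print.al_chamber <- function(x, ...) {
  cat(sprintf(
    "<al_chamber> %g x %g x %g mm, fluid %s, Z_top = %g, Z_side = %g MPa s/m\n",
    x$lateral_size[1] * 1e3, x$lateral_size[2] * 1e3, x$fluid_height * 1e3,
    x$fluid$name, x$top_impedance / 1e6, x$side_impedance / 1e6))
  invisible(x)
}

#' Reference device configurations
#'
#' `model_a_config()` is the homogeneous-array scenario: every PZT unit
#' vibrates at 1.15 nm/V and the epoxy kerf at 0.6 nm/V.
#' `model_b_config()` is the measured inhomogeneous scenario: the centre
#' unit (B2) at 1.7 nm/V, edge units (A2, B1, B3, C2) at 1.2 nm/V, corner
#' units (A1, A3, C1, C3) at 1.0 nm/V, epoxy at 0.6 nm/V. Both drive at
#' 60 V and 660 kHz over a 1.1 mm water column with a 13 MPa s/m glass lid
#' and 17 MPa s/m aluminium side walls.
#'
#' @return A list with elements `chamber` (an `al_chamber`) and `map`
#'   (an `al_transducer_map`).
#' @examples
#' cfg <- model_a_config()
#' cfg$map$units[2, 2] * cfg$map$drive_voltage # 69 nm at the centre unit
#' @export
model_a_config <- function() {
  map <- transducer_map(units = matrix(1.15e-9, 3, 3), epoxy = 0.6e-9)
  list(chamber = chamber_config(), map = map)
}

#' @rdname model_a_config
#' @export
model_b_config <- function() {
  u <- matrix(1.0e-9, 3, 3)           # corners
  u[2, ] <- u[, 2] <- 1.2e-9          # edges
  u[2, 2] <- 1.7e-9                   # centre
  map <- transducer_map(units = u, epoxy = 0.6e-9)
  list(chamber = chamber_config(), map = map)
}

#' Normal displacement amplitude of the chamber floor at a point
#'
#' Piecewise-constant map: a point inside a unit footprint returns that
#' unit's displacement-per-volt times the drive voltage; any other point
#' (the kerf and the margin around the array) returns the epoxy value.
#' Vectorised over `x` and `y` (recycled to a common length).
#'
#' @param map An `al_transducer_map`.
#' @param x,y Coordinates in m, origin at the array centre.
#' @param chamber Optional `al_chamber`; if supplied, points outside the
#'   chamber footprint raise an error.
#' @return Displacement amplitude(s) in m.
#' @examples
#' m <- model_a_config()$map
#' displacement_at(m, 0, 0)        # 69 nm (centre of centre unit)
#' displacement_at(m, 1.2e-3, 0)   # 36 nm (kerf midway between units)
#' @export
displacement_at <- function(map, x, y, chamber = NULL) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (!is.null(chamber)) {
    if (any(abs(x) > chamber$lateral_size[1] / 2 + 1e-12) ||
        any(abs(y) > chamber$lateral_size[2] / 2 + 1e-12))
      stop("point outside the chamber footprint")
  }
  ctr <- unit_centers(map)
  val <- rep(map$epoxy, n)
  half <- map$unit_size / 2
  for (i in seq_along(ctr$x)) for (j in seq_along(ctr$y)) {
    inside <- abs(x - ctr$x[i]) <= half & abs(y - ctr$y[j]) <= half
    val[inside] <- map$units[i, j]
  }
  val * map$drive_voltage
}

# Displacement matrix evaluated on a grid (outer product of axis vectors).
displacement_grid <- function(map, x, y) {
  m <- matrix(map$epoxy, length(x), length(y))
  ctr <- unit_centers(map)
  half <- map$unit_size / 2
  for (i in seq_along(ctr$x)) for (j in seq_along(ctr$y)) {
    ix <- abs(x - ctr$x[i]) <= half
    iy <- abs(y - ctr$y[j]) <= half
    m[ix, iy] <- map$units[i, j]
  }
  m * map$drive_voltage
}
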