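#' Define an acoustic medium
#'
#' Builds a material record from the two primitive acoustic properties,
#' density and sound speed. Compressibility and characteristic impedance are
#' derived: \eqn{\kappa = 1/(\rho c^2)} and \eqn{Z = \rho c}.
#'
#' @param name Character label, e.g. `"water"`.
#' @param density Mass density \eqn{\rho} in kg/m^3. Must be positive.
#' @param sound_speed Speed of sound \eqn{c} in m/s. Must be positive.
#'
#' @return An object of class `al_material`: a list with fields `name`,
#'   `density`, `sound_speed`, `compressibility` (1/Pa) and `impedance`
#'   (Pa s/m).
#'
#' @examples
#' w <- make_material("water", 1000, 1480)
#' w$compressibility # 4.565e-10 1/Pa
#' w$impedance       # 1.48e6 Pa s/m
#' @export
make_material <- function(name, density, sound_speed) {
  if (!is.character(name) || length(name) != 1L)
    stop("'name' must be a single character string")
  check_positive_scalar(density, "density")
  check_positive_scalar(sound_speed, "sound_speed")
  structure(
    list(
      name = name,
      density = density,
      sound_speed = sound_speed,
      compressibility = 1 / (density * sound_speed^2),
      impedance = density * sound_speed
    ),
    class = "al_material"
  )
}

#' @export
print.al_material <- function(x, ...) {
  cat(sprintf(
    "<al_material> %s: rho = %g kg/m^3, c = %g m/s, kappa = %.4g 1/Pa, Z = %.4g Pa s/m\n",
    x$name, x$density, x$sound_speed, x$compressibility, x$impedance))
  invisible(x)
}

#' Water at room temperature, the default chamber fluid
#'
#' The hydrogel precursor filling the chamber is more than 80% water and is
#' treated as acoustically water-like (rho = 1000 kg/m^3, c = 1480 m/s).
#'
#' @return An `al_material`.
#' @export
water <- function() make_material("water", 1000, 1480)

#' Define a spherical particle (spheroid) for acoustophoresis
#'
#' @param radius Sphere radius in m. Must be positive.
#' @param density Particle density in kg/m^3; tissue spheroids are close to
#'   1099 kg/m^3.
#' @param compressibility Particle compressibility in 1/Pa. Default 4.0e-10
#'   is tissue-like (slightly stiffer than water).
#'
#' @return An object of class `al_particle` with fields `radius`, `density`,
#'   `compressibility` and the derived `volume` \eqn{(4/3)\pi a^3}.
#' @examples
#' sp <- particle_spec(radius = 75e-6, density = 1099)
#' sp$volume
#' @export
particle_spec <- function(radius, density = 1099, compressibility = 4.0e-10) {
  check_positive_scalar(radius, "radius")
  check_positive_scalar(density, "density")
  check_positive_scalar(compressibility, "compressibility")
  structure(
    list(radius = radius, density = density,
         compressibility = compressibility,
         volume = (4 / 3) * pi * radius^3),
    class = "al_particle"
  )
}

#' @export
print.al_particle <- function(x, ...) {
  cat(sprintf(
    "<al_particle> a = %g um, rho = %g kg/m^3, kappa = %.3g 1/Pa, V = %.4g m^3\n",
    x$radius * 1e6, x$density, x$compressibility, x$volume))
  invisible(x)
}

# Shared argument validation: positive finite scalar, error names the field.
check_positive_scalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite number (got %s)",
                 field, paste(format(x), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

check_nonnegative_scalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a non-negative finite number (got %s)",
                 field, paste(format(x), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
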