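#' Acoustic contrast (scattering) coefficients
#'
#' Monopole and dipole scattering coefficients of a small compressible
#' sphere in an inviscid fluid:
#' \deqn{f_1 = 1 - \kappa_p/\kappa_m, \qquad
#'       f_2 = \frac{2(\rho_p - \rho_m)}{2\rho_p + \rho_m},}
#' together with the planar-standing-wave contrast factor
#' \eqn{\Phi = f_1/3 + f_2/2} (used by the closed-form oracle). Positive
#' \eqn{\Phi} means the particle is driven toward pressure nodes.
#'
#' @param particle An `al_particle`.
#' @param medium An `al_material`.
#' @return A list with `f1`, `f2`, `phi`.
#' @examples
#' cf <- contrast_factors(particle_spec(75e-6, 1099), water())
#' cf$f2 # 198/3198
#' @export
contrast_factors <- function(particle, medium) {
  stopifnot(inherits(particle, "al_particle"), inherits(medium, "al_material"))
  f1 <- 1 - particle$compressibility / medium$compressibility
  f2 <- 2 * (particle$density - medium$density) /
    (2 * particle$density + medium$density)
  list(f1 = f1, f2 = f2, phi = f1 / 3 + f2 / 2)
}

#' Gor'kov radiation potential on a solved field
#'
#' Time-averaged radiation potential of a sub-wavelength compressible
#' sphere in the complex-amplitude field \eqn{(p, v)}:
#' \deqn{U = V \left[ f_1 \frac{\langle p^2\rangle}{2 \rho_m c^2}
#'   - f_2 \frac{3}{4} \rho_m \langle v^2 \rangle \right],}
#' with \eqn{\langle p^2\rangle = |p|^2/2} and
#' \eqn{\langle v^2 \rangle = |v|^2/2} (the \eqn{e^{-i\omega t}}
#' convention). Valid for particle radius much smaller than the wavelength;
#' a warning is raised for \eqn{a > \lambda/10}.
#'
#' @param fld An `al_field`.
#' @param particle An `al_particle`.
#' @return An object of class `al_potential`: grid vectors plus the real
#'   array `U` (J) and the `particle`.
#' @export
gorkov_potential <- function(fld, particle) {
  stopifnot(inherits(fld, "al_field"), inherits(particle, "al_particle"))
  med <- fld$medium
  lambda <- 2 * pi / Re(fld$k)
  if (particle$radius > lambda / 10)
    warning(sprintf(
      "particle radius %.3g m exceeds lambda/10 = %.3g m; Gor'kov theory is marginal",
      particle$radius, lambda / 10))
  cf <- contrast_factors(particle, med)
  msq_p <- abs(fld$p)^2 / 2
  msq_v <- (abs(fld$vx)^2 + abs(fld$vy)^2 + abs(fld$vz)^2) / 2
  U <- particle$volume *
    (cf$f1 * msq_p / (2 * med$density * med$sound_speed^2) -
       cf$f2 * (3 / 4) * med$density * msq_v)
  structure(
    list(x = fld$x, y = fld$y, z = fld$z, U = U, particle = particle,
         quarter = fld$quarter, field = fld),
    class = "al_potential")
}

#' @export
print.al_potential <- function(x, ...) {
  cat(sprintf("<al_potential> %d x %d x %d grid, U in [%.3g, %.3g] J\n",
              length(x$x), length(x$y), length(x$z), min(x$U), max(x$U)))
  invisible(x)
}

#' Acoustic radiation force field
#'
#' The radiation force is the negative gradient of the Gor'kov potential,
#' \eqn{F = -\nabla U}, evaluated by central differences (one-sided at
#' grid boundaries).
#'
#' @param potential An `al_potential`.
#' @return An object of class `al_force`: grid vectors plus real arrays
#'   `Fx`, `Fy`, `Fz` (N) and the `particle`.
#' @export
radiation_force <- function(potential) {
  stopifnot(inherits(potential, "al_potential"))
  structure(
    list(x = potential$x, y = potential$y, z = potential$z,
         Fx = -array_gradient(potential$U, potential$x, 1),
         Fy = -array_gradient(potential$U, potential$y, 2),
         Fz = -array_gradient(potential$U, potential$z, 3),
         U = potential$U,
         particle = potential$particle,
         quarter = potential$quarter,
         field = potential$field),
    class = "al_force")
}

#' @export
print.al_force <- function(x, ...) {
  cat(sprintf("<al_force> %d x %d x %d grid, max|Fz| = %.4g N\n",
              length(x$x), length(x$y), length(x$z), max(abs(x$Fz))))
  invisible(x)
}

#' Per-unit vertical radiation force comparison
#'
#' Evaluates the maximum vertical radiation-force magnitude along the
#' vertical line through the centre of a representative unit of each
#' symmetry class of the array (centre, edge, corner for a 3 x 3), the way
#' per-unit force profiles are plotted, and reports each class's ratio to
#' the centre unit.
#'
#' @param fld An `al_field` solved from a 3 x 3 array configuration.
#' @param particle An `al_particle`.
#' @param z_window Optional length-2 height window (m) restricting the
#'   search, e.g. a neighbourhood of the node plane. Default: full column.
#' @return A data.frame with columns `unit_class`, `max_Fz` (N) and
#'   `center_ratio` (centre force / class force).
#' @export
unit_force_comparison <- function(fld, particle, z_window = NULL) {
  force <- radiation_force(gorkov_potential(fld, particle))
  pitch <- fld$map$pitch
  classes <- list(center = c(0, 0), edge = c(pitch, 0),
                  corner = c(pitch, pitch))
  iz <- if (is.null(z_window)) seq_along(fld$z)
        else which(fld$z >= z_window[1] & fld$z <= z_window[2])
  vals <- vapply(classes, function(ctr) {
    xq <- if (force$quarter["x"]) abs(ctr[1]) else ctr[1]
    yq <- if (force$quarter["y"]) abs(ctr[2]) else ctr[2]
    ix <- which.min(abs(force$x - xq))
    iy <- which.min(abs(force$y - yq))
    max(abs(force$Fz[ix, iy, iz]))
  }, numeric(1))
  data.frame(unit_class = names(classes), max_Fz = unname(vals),
             center_ratio = unname(vals["center"] / vals),
             row.names = NULL)
}

#' Analytic planar standing-wave field
#'
#' Builds an `al_field` for the closed-form planar standing wave
#' \eqn{p = P\cos(kz)}, \eqn{v_z = i (P/\rho c) \sin(kz)} on a given
#' z grid (laterally uniform). Used as the analytic oracle for the Gor'kov
#' implementation; the corresponding closed-form axial force is
#' \deqn{F_z(z) = 4\pi \Phi k a^3 E_{ac} \sin(2 k z), \qquad
#'  E_{ac} = P^2 / (4 \rho c^2).}
#'
#' @param P Pressure amplitude, Pa.
#' @param medium An `al_material`.
#' @param f Frequency, Hz.
#' @param z Vector of heights, m.
#' @param nx Number of (dummy) lateral grid points.
#' @param Lx Lateral extent of the dummy grid, m.
#' @return An `al_field` with exact analytic `p` and `v`.
#' @export
planar_standing_wave <- function(P, medium, f, z, nx = 3, Lx = 1e-3) {
  om <- 2 * pi * f
  k <- om / medium$sound_speed
  x <- seq(0, Lx, length.out = nx)
  nz <- length(z)
  pz <- P * cos(k * z)
  vz <- 1i * (P / (medium$density * medium$sound_speed)) * sin(k * z)
  rep_grid <- function(vec) aperm(array(vec, c(nz, nx, nx)), c(2, 3, 1))
  structure(
    list(x = x, y = x, z = z,
         p = rep_grid(pz) + 0i,
         vx = rep_grid(rep(0 + 0i, nz)), vy = rep_grid(rep(0 + 0i, nz)),
         vz = rep_grid(vz),
         omega = om, k = k, medium = medium, chamber = NULL, map = NULL,
         quarter = c(x = FALSE, y = FALSE),
         resolution = c(Lx / (nx - 1), Lx / (nx - 1), z[2] - z[1])),
    class = "al_field")
}
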