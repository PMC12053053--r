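# Trilinear interpolation of a 3D array at one point (x, y, z inside grid).
interp3 <- function(ax, ay, az, arr, pt) {
  loc <- function(coord, v) {
    i <- findInterval(v, coord, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(coord) - 1L)
    w <- (v - coord[i]) / (coord[i + 1] - coord[i])
    list(i = i, w = w)
  }
  lx <- loc(ax, pt[1]); ly <- loc(ay, pt[2]); lz <- loc(az, pt[3])
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) lx$w else 1 - lx$w) *
          (if (dy) ly$w else 1 - ly$w) *
          (if (dz) lz$w else 1 - lz$w)
    acc <- acc + wt * arr[lx$i + dx, ly$i + dy, lz$i + dz]
  }
  acc
}

# Radiation force at a point; quarter-domain fields are unfolded by mirror
# symmetry (|x| lookup, odd Fx / Fy across the respective plane).
force_at <- function(force, pt) {
  sx <- 1; sy <- 1
  x <- pt[1]; y <- pt[2]
  if (force$quarter["x"]) { sx <- ifelse(x < 0, -1, 1); x <- abs(x) }
  if (force$quarter["y"]) { sy <- ifelse(y < 0, -1, 1); y <- abs(y) }
  if (x < min(force$x) - 1e-12 || x > max(force$x) + 1e-12 ||
      y < min(force$y) - 1e-12 || y > max(force$y) + 1e-12 ||
      pt[3] < min(force$z) - 1e-12 || pt[3] > max(force$z) + 1e-12)
    stop(sprintf("position (%.3g, %.3g, %.3g) outside the field domain",
                 pt[1], pt[2], pt[3]))
  q <- c(x, y, pt[3])
  c(sx * interp3(force$x, force$y, force$z, force$Fx, q),
    sy * interp3(force$x, force$y, force$z, force$Fy, q),
    interp3(force$x, force$y, force$z, force$Fz, q))
}

gorkov_at <- function(force, pt) {
  x <- if (force$quarter["x"]) abs(pt[1]) else pt[1]
  y <- if (force$quarter["y"]) abs(pt[2]) else pt[2]
  interp3(force$x, force$y, force$z, force$U, c(x, y, pt[3]))
}

#' Net force on a particle at a position
#'
#' Sum of the interpolated acoustic radiation force and the
#' buoyancy-corrected weight \eqn{(\rho_m - \rho_p) V g \hat z}. Stokes
#' drag is velocity-dependent and belongs to the integrator, not here.
#'
#' @param particle An `al_particle`.
#' @param position Length-3 numeric (x, y, z) in m.
#' @param force_field An `al_force`, or `NULL` for no acoustic field.
#' @param medium An `al_material` (the suspending fluid).
#' @param g Gravitational acceleration, m/s^2.
#' @param buoyancy If `FALSE`, the plain weight \eqn{-\rho_p V g \hat z} is
#'   used (no Archimedes term).
#' @return Length-3 force vector in N.
#' @examples
#' sp <- particle_spec(75e-6, 1099)
#' net_force(sp, c(0, 0, 5e-4), NULL, water()) # ~1.72 nN downward
#' @export
net_force <- function(particle, position, force_field, medium, g = 9.81,
                      buoyancy = TRUE) {
  stopifnot(inherits(particle, "al_particle"), length(position) == 3)
  frad <- if (is.null(force_field)) c(0, 0, 0) else force_at(force_field, position)
  rho_ref <- if (buoyancy) medium$density else 0
  frad + c(0, 0, (rho_ref - particle$density) * particle$volume * g)
}

#' Overdamped levitation trajectory
#'
#' Integrates the overdamped equation of motion
#' \eqn{\dot x = F_{net}(x) / (6\pi\mu a)} with an adaptive explicit Heun
#' scheme whose step size is controlled by a displacement limit. Inertia is
#' neglected: the momentum relaxation time \eqn{2 a^2 \rho_p / (9\mu)} is
#' about a millisecond for a 150 um spheroid in a water-like precursor,
#' orders of magnitude below the seconds-scale transport. The particle
#' centre is confined to `[a, h - a]` vertically (floor/lid contact is
#' treated as resting: the into-wall force component is dropped while in
#' contact) and to the chamber laterally.
#'
#' @param particle An `al_particle`.
#' @param start Length-3 starting position, m.
#' @param force_field An `al_force` (or `NULL`: sedimentation only).
#' @param medium An `al_material`.
#' @param viscosity Dynamic viscosity, Pa s. Default 1e-3 (water-like).
#' @param dt Maximum time step, s.
#' @param t_end Integration horizon, s.
#' @param g Gravitational acceleration, m/s^2.
#' @param chamber An `al_chamber` giving the bounds; defaults to the field's
#'   chamber (required when `force_field` is `NULL`).
#' @param step_limit Maximum displacement per step, m.
#' @param position_tolerance Convergence threshold: the run stops early once
#'   a full-size step moves the particle less than this, m.
#' @return An object of class `al_trajectory`: data.frame `path` with
#'   columns `t`, `x`, `y`, `z`; `terminal_position`; logical `converged`.
#' @export
simulate_trajectory <- function(particle, start, force_field, medium,
                                viscosity = 1e-3, dt = 5e-3, t_end = 20,
                                g = 9.81, chamber = NULL,
                                step_limit = 10e-6,
                                position_tolerance = 1e-8) {
  check_positive_scalar(viscosity, "viscosity")
  check_positive_scalar(dt, "dt")
  if (is.null(chamber)) chamber <- force_field$field$chamber %||% force_field$chamber
  if (is.null(chamber)) stop("supply 'chamber' when 'force_field' carries none")
  gamma <- 6 * pi * viscosity * particle$radius
  lo <- c(-chamber$lateral_size[1] / 2, -chamber$lateral_size[2] / 2,
          particle$radius)
  hi <- c(chamber$lateral_size[1] / 2, chamber$lateral_size[2] / 2,
          chamber$fluid_height - particle$radius)
  clamp <- function(p) pmin(pmax(p, lo), hi)
  # drop force components pushing into an active wall contact
  constrain <- function(p, f) {
    at_lo <- p <= lo + 1e-12; at_hi <- p >= hi - 1e-12
    f[at_lo & f < 0] <- 0
    f[at_hi & f > 0] <- 0
    f
  }
  # total potential driving the overdamped descent (radiation + net weight);
  # used to enforce monotone energy decrease (backtracking step acceptance)
  U_tot <- function(p) {
    u_rad <- if (is.null(force_field)) 0 else gorkov_at(force_field, p)
    u_rad + (particle$density - medium$density) * particle$volume * g * p[3]
  }
  pos <- clamp(as.numeric(start))
  t <- 0
  ts <- t; path <- matrix(pos, nrow = 1)
  converged <- FALSE
  while (t < t_end) {
    f1 <- constrain(pos, net_force(particle, pos, force_field, medium, g))
    if (any(!is.finite(f1)))
      stop(sprintf("non-finite force at (%.3g, %.3g, %.3g)",
                   pos[1], pos[2], pos[3]))
    v1 <- f1 / gamma
    speed <- sqrt(sum(v1^2))
    h_step <- if (speed > 0) min(dt, step_limit / speed, t_end - t) else
      min(dt, t_end - t)
    full_step <- h_step >= min(dt, t_end - t) - 1e-15
    # Heun predictor-corrector; halve the step while it climbs the potential
    U0 <- U_tot(pos)
    h_min <- h_step / 4096
    repeat {
      pred <- clamp(pos + h_step * v1)
      f2 <- constrain(pred, net_force(particle, pred, force_field, medium, g))
      newpos <- clamp(pos + h_step * (v1 + f2 / gamma) / 2)
      if (U_tot(newpos) <= U0 || h_step <= h_min) break
      h_step <- h_step / 2
    }
    if (U_tot(newpos) > U0) {
      # no descent direction at the minimum step: discrete potential minimum
      converged <- TRUE
      break
    }
    moved <- sqrt(sum((newpos - pos)^2))
    t <- t + h_step
    pos <- newpos
    ts <- c(ts, t); path <- rbind(path, pos)
    if (full_step && moved < position_tolerance) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(path = data.frame(t = ts, x = path[, 1], y = path[, 2], z = path[, 3]),
         terminal_position = pos, converged = converged,
         particle = particle, viscosity = viscosity),
    class = "al_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.al_trajectory <- function(x, ...) {
  tp <- x$terminal_position
  cat(sprintf(
    "<al_trajectory> %d steps over %.3g s; terminal (%.3g, %.3g, %.3g) mm; converged: %s\n",
    nrow(x$path) - 1, max(x$path$t), tp[1] * 1e3, tp[2] * 1e3, tp[3] * 1e3,
    x$converged))
  invisible(x)
}

#' Levitation equilibrium height on a vertical line
#'
#' Finds the height where the vertical net force (interpolated radiation
#' force plus buoyancy-corrected weight) vanishes, taking the stable root
#' nearest below the pressure node of the column at `(x, y)`; the root is
#' polished by bracketed bisection ([stats::uniroot]) to 0.1 um.
#'
#' @param particle An `al_particle`.
#' @param force_field An `al_force` built from a solved field.
#' @param x,y Lateral position, m.
#' @param g Gravitational acceleration, m/s^2.
#' @return Equilibrium height z in m. Errors if no bracketing interval
#'   exists (the column is not levitatable, e.g. the field is too weak).
#' @export
equilibrium_height <- function(particle, force_field, x, y, g = 9.81) {
  medium <- force_field$field$medium
  fz <- function(z) net_force(particle, c(x, y, z), force_field, medium, g)[3]
  zlo <- min(force_field$z) + particle$radius
  zhi <- max(force_field$z) - particle$radius
  zs <- seq(zlo, zhi, length.out = 400)
  v <- vapply(zs, fz, numeric(1))
  # stable equilibria: force changes + -> - going up
  idx <- which(v[-length(v)] > 0 & v[-1] <= 0)
  if (length(idx) == 0)
    stop("no stable force equilibrium on this column: not levitatable here")
  node <- if (!is.null(force_field$field)) node_plane(force_field$field, x, y)
          else NA_real_
  pick <- if (is.finite(node)) {
    below <- idx[zs[idx] <= node + 1e-6]
    if (length(below)) max(below) else idx[which.min(abs(zs[idx] - node))]
  } else max(idx)
  stats::uniroot(fz, lower = zs[pick], upper = zs[pick + 1], tol = 1e-7)$root
}

#' Lateral acoustic trap positions on the node plane
#'
#' Restricts the Gor'kov potential to the node plane and reports the
#' potential minimum within each transducer-unit footprint (one trap per
#' unit). Quarter-domain solutions are unfolded to the full array by
#' mirror symmetry. A laterally uniform potential (relative lateral
#' modulation below `tol`) yields zero traps with attribute
#' `"degenerate" = TRUE`.
#'
#' @param force_field An `al_force` (carries U and the map via its field).
#' @param particle An `al_particle` (for interface symmetry; the trap
#'   layout is particle-independent up to the sign of the contrast factor).
#' @param tol Relative lateral-modulation threshold for degeneracy.
#' @return A data.frame with columns `x`, `y`, `z`, `U`.
#' @export
trap_positions <- function(force_field, particle, tol = 1e-6) {
  fld <- force_field$field
  if (is.null(fld) || is.null(fld$map))
    stop("force field does not carry its source field/map")
  zc <- node_plane(fld, 0, 0)
  if (!is.finite(zc)) stop("no node plane found")
  iz <- which.min(abs(fld$z - zc))
  Uslice <- force_field$U[, , iz]
  if (diff(range(Uslice)) < tol * max(abs(Uslice))) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      U = numeric(0))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ctr <- unit_centers(fld$map)
  half <- fld$map$unit_size / 2
  rows <- list()
  for (cx in ctr$x) for (cy in ctr$y) {
    qx <- if (fld$quarter["x"]) abs(cx) else cx
    qy <- if (fld$quarter["y"]) abs(cy) else cy
    if (fld$quarter["x"] && cx < 0 || fld$quarter["y"] && cy < 0) {
      # mirrored copy of a solved unit: reuse the mirrored minimum
      ix <- which(abs(fld$x - qx) <= half)
      iy <- which(abs(fld$y - qy) <= half)
    } else {
      ix <- which(abs(fld$x - qx) <= half)
      iy <- which(abs(fld$y - qy) <= half)
    }
    sub <- Uslice[ix, iy, drop = FALSE]
    m <- arrayInd(which.min(sub), dim(sub))
    tx <- fld$x[ix[m[1]]] * if (cx < 0 && fld$quarter["x"]) -1 else 1
    ty <- fld$y[iy[m[2]]] * if (cy < 0 && fld$quarter["y"]) -1 else 1
    rows[[length(rows) + 1]] <-
      data.frame(x = tx, y = ty, z = fld$z[iz], U = min(sub))
  }
  out <- do.call(rbind, rows)
  attr(out, "degenerate") <- FALSE
  out
}
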