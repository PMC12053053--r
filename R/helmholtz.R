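#' Frequency-domain pressure solver for the levitation chamber
#'
#' Solves the Helmholtz equation \eqn{\nabla^2 p + k^2 p = 0} on a regular
#' structured grid over the chamber, with
#' \itemize{
#'   \item displacement-driven floor: \eqn{\partial p/\partial z =
#'     \rho\omega^2 D(x, y)} at z = 0, where D is the transducer map;
#'   \item impedance (Robin) lid and side walls: \eqn{\partial p/\partial n
#'     = i\omega\rho\, p / Z} (outward normal), rigid for `Z = Inf`;
#'   \item homogeneous Neumann mirror planes at x = 0 / y = 0 when the
#'     chamber is flagged symmetric, in which case only the quarter domain
#'     is discretised.
#' }
#' Discretisation is second-order central finite differences with
#' ghost-point boundary closure. Because the discrete operator is separable
#' (a box with axis-aligned boundary conditions and constant k), the linear
#' system is solved directly by eigendecomposition of the 1D x/y operators
#' and per-mode solves along z, which is exact for the discretised system
#' (see the methods vignette). The acoustic velocity
#' \eqn{v = \nabla p / (i\omega\rho)} is evaluated from the solved pressure
#' by finite differences.
#'
#' @param chamber An `al_chamber`.
#' @param map An `al_transducer_map` (its `frequency` sets \eqn{\omega}).
#' @param resolution Numeric length-3 `(dx, dy, dz)` in m. Must satisfy
#'   `dx, dy <= lambda/10` and `dz <= lambda/15`.
#' @param loss Optional relative loss factor on the wavenumber (default 0).
#' @return An object of class `al_field`: axis vectors `x`, `y`, `z` (m),
#'   complex arrays `p` (Pa) and `vx`, `vy`, `vz` (m/s), plus `omega`,
#'   `k`, `medium`, `chamber`, `map` and the per-axis `quarter` flags.
#' @examples
#' \donttest{
#' cfg <- model_a_config()
#' fld <- solve_pressure(cfg$chamber, cfg$map)
#' max(abs(fld$p)) / 1e6 # MPa
#' }
#' @export
solve_pressure <- function(chamber, map,
                           resolution = c(100e-6, 100e-6, 50e-6),
                           loss = 0) {
  stopifnot(inherits(chamber, "al_chamber"), inherits(map, "al_transducer_map"))
  if (length(resolution) != 3 || any(resolution <= 0))
    stop("'resolution' must be positive (dx, dy, dz) in m")
  med <- chamber$fluid
  om <- 2 * pi * map$frequency
  lambda <- med$sound_speed / map$frequency
  if (resolution[3] > lambda / 15)
    stop(sprintf("vertical resolution too coarse: dz must be <= lambda/15 = %.3g m",
                 lambda / 15))
  if (any(resolution[1:2] > lambda / 10))
    stop(sprintf("lateral resolution too coarse: dx, dy must be <= lambda/10 = %.3g m",
                 lambda / 10))
  if (array_footprint(map) > min(chamber$lateral_size))
    stop("chamber lateral size is smaller than the transducer array footprint")

  k <- (om / med$sound_speed) * (1 + 1i * loss)
  rho <- med$density

  ax <- axis_setup(chamber$lateral_size[1], resolution[1], chamber$symmetry[1])
  ay <- axis_setup(chamber$lateral_size[2], resolution[2], chamber$symmetry[2])
  nz <- max(4L, round(chamber$fluid_height / resolution[3]) + 1L)
  z <- seq(0, chamber$fluid_height, length.out = nz)
  dz <- z[2] - z[1]

  Ax <- fd_operator(length(ax$coord), ax$coord[2] - ax$coord[1],
                    ax$lo, "imp", om, rho, Z_hi = chamber$side_impedance)
  Ay <- fd_operator(length(ay$coord), ay$coord[2] - ay$coord[1],
                    ay$lo, "imp", om, rho, Z_hi = chamber$side_impedance)
  Az <- fd_operator(nz, dz, "neu", "imp", om, rho, Z_hi = chamber$top_impedance)

  ex <- eigen(Ax); ey <- eigen(Ay)
  Vxi <- solve(ex$vectors); Vyi <- solve(ey$vectors)

  nx <- length(ax$coord); ny <- length(ay$coord)
  b <- array(0 + 0i, c(nx, ny, nz))
  D <- displacement_grid(map, ax$coord, ay$coord)
  b[, , 1] <- 2 * rho * om^2 * D / dz

  bt <- array(0 + 0i, c(nx, ny, nz))
  for (iz in seq_len(nz)) bt[, , iz] <- Vxi %*% b[, , iz] %*% t(Vyi)
  pt <- array(0 + 0i, c(nx, ny, nz))
  Iz <- diag(nz)
  for (i in seq_len(nx)) {
    shift_i <- ex$values[i] + k^2
    for (j in seq_len(ny)) {
      M <- Az + (shift_i + ey$values[j]) * Iz
      pt[i, j, ] <- solve(M, bt[i, j, ])
    }
  }
  p <- array(0 + 0i, c(nx, ny, nz))
  for (iz in seq_len(nz)) p[, , iz] <- ex$vectors %*% pt[, , iz] %*% t(ey$vectors)

  fld <- structure(
    list(x = ax$coord, y = ay$coord, z = z, p = p,
         omega = om, k = k, medium = med, chamber = chamber, map = map,
         quarter = c(x = isTRUE(chamber$symmetry[1]),
                     y = isTRUE(chamber$symmetry[2])),
         resolution = resolution),
    class = "al_field")
  fld[c("vx", "vy", "vz")] <- field_velocity(fld)
  # parity: the normal velocity vanishes identically on a mirror plane
  if (fld$quarter["x"]) fld$vx[1, , ] <- 0 + 0i
  if (fld$quarter["y"]) fld$vy[, 1, ] <- 0 + 0i
  fld
}

# Axis coordinates: quarter [0, L/2] with symmetry closure at 0, or full
# [-L/2, L/2] with impedance closure on both ends.
axis_setup <- function(L, d, symmetric) {
  if (symmetric) {
    n <- max(4L, round((L / 2) / d) + 1L)
    list(coord = seq(0, L / 2, length.out = n), lo = "sym")
  } else {
    n <- max(5L, round(L / d) + 1L)
    list(coord = seq(-L / 2, L / 2, length.out = n), lo = "imp")
  }
}

# 1D second-difference operator with ghost-point boundary closure.
# bc codes: "sym"/"neu" homogeneous Neumann, "imp" Robin dp/dn = i w rho p / Z.
fd_operator <- function(n, d, bc_lo, bc_hi, om, rho, Z_lo = NULL, Z_hi = NULL) {
  A <- matrix(0 + 0i, n, n)
  for (i in 2:(n - 1)) { A[i, i - 1] <- 1; A[i, i] <- -2; A[i, i + 1] <- 1 }
  zfac <- function(Z) if (is.null(Z) || is.infinite(Z)) 0 else 1i * om * rho / Z
  A[1, 2] <- 2
  A[1, 1] <- -2 + if (bc_lo == "imp") 2 * d * zfac(if (is.null(Z_lo)) Z_hi else Z_lo) else 0
  A[n, n - 1] <- 2
  A[n, n] <- -2 + if (bc_hi == "imp") 2 * d * zfac(Z_hi) else 0
  A / d^2
}

# v = grad p / (i w rho), central differences (one-sided at boundaries).
field_velocity <- function(fld) {
  fac <- 1 / (1i * fld$omega * fld$medium$density)
  list(vx = array_gradient(fld$p, fld$x, 1) * fac,
       vy = array_gradient(fld$p, fld$y, 2) * fac,
       vz = array_gradient(fld$p, fld$z, 3) * fac)
}

# Gradient of a 3D array along one axis; second-order central in the
# interior, first-order one-sided at the two boundary layers.
array_gradient <- function(arr, coord, axis) {
  n <- dim(arr)[axis]
  d <- coord[2] - coord[1]
  g <- array(if (is.complex(arr)) 0 + 0i else 0, dim(arr))
  slice <- function(i) {
    switch(axis, arr[i, , , drop = FALSE], arr[, i, , drop = FALSE],
           arr[, , i, drop = FALSE])
  }
  assign_slice <- function(i, v) {
    switch(axis,
           g[i, , ] <<- v,
           g[, i, ] <<- v,
           g[, , i] <<- v)
  }
  assign_slice(1L, (slice(2L) - slice(1L)) / d)
  assign_slice(n, (slice(n) - slice(n - 1L)) / d)
  if (n > 2) for (i in 2:(n - 1))
    assign_slice(i, (slice(i + 1L) - slice(i - 1L)) / (2 * d))
  g
}

#' @export
print.al_field <- function(x, ...) {
  cat(sprintf(
    "<al_field> %d x %d x %d grid, f = %g kHz; max|p| = %.4g MPa%s\n",
    length(x$x), length(x$y), length(x$z), x$omega / (2 * pi * 1e3),
    max(abs(x$p)) / 1e6,
    if (any(x$quarter)) " (quarter domain)" else ""))
  invisible(x)
}

#' Interior Helmholtz residual of a solved field
#'
#' Evaluates \eqn{\|\nabla^2 p + k^2 p\|_\infty} on interior grid points
#' relative to \eqn{|k|^2 \max|p|}; a converged solve is at discretisation
#' accuracy. Used by the test suite as a field invariant.
#'
#' @param fld An `al_field`.
#' @return Relative residual (dimensionless scalar).
#' @export
helmholtz_residual <- function(fld) {
  p <- fld$p
  d <- c(fld$x[2] - fld$x[1], fld$y[2] - fld$y[1], fld$z[2] - fld$z[1])
  n <- dim(p)
  ii <- 2:(n[1] - 1); jj <- 2:(n[2] - 1); kk <- 2:(n[3] - 1)
  lap <- (p[ii + 1, jj, kk] - 2 * p[ii, jj, kk] + p[ii - 1, jj, kk]) / d[1]^2 +
         (p[ii, jj + 1, kk] - 2 * p[ii, jj, kk] + p[ii, jj - 1, kk]) / d[2]^2 +
         (p[ii, jj, kk + 1] - 2 * p[ii, jj, kk] + p[ii, jj, kk - 1]) / d[3]^2
  res <- lap + fld$k^2 * p[ii, jj, kk]
  max(abs(res)) / (abs(fld$k)^2 * max(abs(p)))
}

#' Mirror a quarter-domain field to the full chamber
#'
#' Reflects the solved quarter field across the x = 0 and/or y = 0 mirror
#' planes. Pressure and `vz` are even under each mirror; the in-plane
#' velocity component normal to a mirror is odd.
#'
#' @param fld An `al_field` solved on a quarter (or half) domain.
#' @return An `al_field` covering the full chamber (`quarter` flags FALSE).
#' @export
reconstruct_full <- function(fld) {
  out <- fld
  if (fld$quarter["x"]) {
    out$x <- c(-rev(out$x[-1]), out$x)
    out$p <- mirror_axis(out$p, 1, even = TRUE)
    out$vx <- mirror_axis(out$vx, 1, even = FALSE)
    out$vy <- mirror_axis(out$vy, 1, even = TRUE)
    out$vz <- mirror_axis(out$vz, 1, even = TRUE)
  }
  if (fld$quarter["y"]) {
    out$y <- c(-rev(out$y[-1]), out$y)
    out$p <- mirror_axis(out$p, 2, even = TRUE)
    out$vx <- mirror_axis(out$vx, 2, even = TRUE)
    out$vy <- mirror_axis(out$vy, 2, even = FALSE)
    out$vz <- mirror_axis(out$vz, 2, even = TRUE)
  }
  out$quarter <- c(x = FALSE, y = FALSE)
  out
}

# Reflect array across the first plane of `axis`; odd components flip sign.
mirror_axis <- function(arr, axis, even = TRUE) {
  d <- dim(arr)
  n <- d[axis]
  nd <- d; nd[axis] <- 2 * n - 1
  out <- array(arr[1] * 0, nd)
  sgn <- if (even) 1 else -1
  idx <- rev(seq_len(n)[-1])
  if (axis == 1) {
    out[seq_len(n - 1), , ] <- sgn * arr[idx, , ]
    out[n:(2 * n - 1), , ] <- arr
  } else if (axis == 2) {
    out[, seq_len(n - 1), ] <- sgn * arr[, idx, ]
    out[, n:(2 * n - 1), ] <- arr
  } else {
    out[, , seq_len(n - 1)] <- sgn * arr[, , idx]
    out[, , n:(2 * n - 1)] <- arr
  }
  out
}

#' Height of the pressure node along a vertical line
#'
#' Extracts |p| along the grid column nearest to `(x, y)` and returns the
#' height of its deepest interior local minimum, refined by three-point
#' parabolic interpolation. Columns with no interior minimum (monotone or
#' modulation below 1% of the column maximum) return `NA`.
#'
#' @param fld An `al_field`.
#' @param x,y Lateral position in m (quarter-domain fields accept the full
#'   coordinate range via mirror symmetry).
#' @return Node height z in m, or `NA_real_` if absent.
#' @examples
#' \donttest{
#' cfg <- model_a_config()
#' fld <- solve_pressure(cfg$chamber, cfg$map)
#' node_plane(fld, 0, 0) * 1e6 # um, above the centre unit
#' }
#' @export
node_plane <- function(fld, x, y) {
  if (fld$quarter["x"]) x <- abs(x)
  if (fld$quarter["y"]) y <- abs(y)
  ix <- which.min(abs(fld$x - x)); iy <- which.min(abs(fld$y - y))
  mag <- abs(fld$p[ix, iy, ])
  nodes <- find_profile_minima(fld$z, mag, prominence = 0.01 * max(mag))
  if (length(nodes) == 0) return(NA_real_)
  depth <- vapply(nodes, function(zz) {
    iz <- which.min(abs(fld$z - zz)); mag[iz]
  }, numeric(1))
  nodes[which.min(depth)]
}

#' Grid-convergence study of the chamber solve
#'
#' Re-solves the chamber at a sequence of resolutions and tabulates the
#' global max |p| and the node height above the array centre, with
#' successive relative changes. Non-monotone behaviour of the changes is
#' flagged in the `monotone` attribute.
#'
#' @param chamber An `al_chamber`.
#' @param map An `al_transducer_map`.
#' @param resolutions List of length-3 numeric resolutions (m), coarsest
#'   first; at least 3.
#' @return A data.frame with columns `dx`, `dy`, `dz`, `max_p`, `node_z`,
#'   `rel_change_max_p`, `rel_change_node_z`.
#' @export
convergence_study <- function(chamber, map, resolutions) {
  if (length(resolutions) < 3) stop("need at least 3 resolutions")
  rows <- lapply(resolutions, function(res) {
    fld <- solve_pressure(chamber, map, resolution = res)
    data.frame(dx = res[1], dy = res[2], dz = res[3],
               max_p = max(abs(fld$p)), node_z = node_plane(fld, 0, 0))
  })
  out <- do.call(rbind, rows)
  out$rel_change_max_p <- c(NA, abs(diff(out$max_p)) / out$max_p[-1])
  out$rel_change_node_z <- c(NA, abs(diff(out$node_z)) /
                               pmax(abs(out$node_z[-1]), .Machine$double.eps))
  ch <- out$rel_change_node_z[-1]
  attr(out, "monotone") <- all(diff(ch[ch > 0]) <= 0) || length(ch) < 2
  out
}
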