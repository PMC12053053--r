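#' Export a field to a legacy-ASCII VTK rectilinear grid
#'
#' Writes `Re p`, `Im p`, `|p|` and `|v|` (and, if supplied, the Gor'kov
#' potential and force vectors) as point data for inspection in ParaView.
#'
#' @param fld An `al_field`.
#' @param path Output file path (`.vtk`).
#' @param force Optional `al_force` on the same grid (adds `U` and `F`).
#' @return The path, invisibly.
#' @export
write_vtk_field <- function(fld, path, force = NULL) {
  nx <- length(fld$x); ny <- length(fld$y); nz <- length(fld$z)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("acoustolev field export")
  wl("ASCII")
  wl("DATASET RECTILINEAR_GRID")
  wl("DIMENSIONS %d %d %d", nx, ny, nz)
  wl("X_COORDINATES %d double", nx)
  writeLines(paste(format(fld$x, digits = 9), collapse = " "), con)
  wl("Y_COORDINATES %d double", ny)
  writeLines(paste(format(fld$y, digits = 9), collapse = " "), con)
  wl("Z_COORDINATES %d double", nz)
  writeLines(paste(format(fld$z, digits = 9), collapse = " "), con)
  wl("POINT_DATA %d", nx * ny * nz)
  # VTK expects x fastest; R arrays are already column-major in (x, y, z)
  scalar <- function(name, arr) {
    wl("SCALARS %s double 1", name)
    wl("LOOKUP_TABLE default")
    writeLines(format(as.vector(arr), digits = 7), con)
  }
  scalar("p_re", Re(fld$p))
  scalar("p_im", Im(fld$p))
  scalar("p_abs", abs(fld$p))
  scalar("v_abs", sqrt(abs(fld$vx)^2 + abs(fld$vy)^2 + abs(fld$vz)^2))
  if (!is.null(force)) {
    scalar("U", force$U)
    wl("VECTORS F double")
    writeLines(paste(format(as.vector(force$Fx), digits = 7),
                     format(as.vector(force$Fy), digits = 7),
                     format(as.vector(force$Fz), digits = 7)), con)
  }
  invisible(path)
}

#' Vertical line probe of a field
#'
#' @param fld An `al_field`.
#' @param x,y Lateral position, m (nearest grid column).
#' @return A data.frame with `z`, `p_re`, `p_im`, `p_abs`.
#' @export
probe_column <- function(fld, x = 0, y = 0) {
  if (fld$quarter["x"]) x <- abs(x)
  if (fld$quarter["y"]) y <- abs(y)
  ix <- which.min(abs(fld$x - x)); iy <- which.min(abs(fld$y - y))
  p <- fld$p[ix, iy, ]
  data.frame(z = fld$z, p_re = Re(p), p_im = Im(p), p_abs = abs(p))
}
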