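#' Closed-form driven acoustic column (1D)
#'
#' Solves the 1D Helmholtz problem for a fluid column of height `h` driven
#' by a piston of displacement amplitude `bottom_displacement` at `z = 0`
#' and closed by an impedance lid at `z = h`:
#' \deqn{p(z) = A e^{ikz} + B e^{-ikz}}
#' with boundary conditions (package-wide \eqn{e^{-i\omega t}} convention)
#' \deqn{p'(0) = \rho \omega^2 D, \qquad p'(h) = i\omega\rho\, p(h) / Z_{top}.}
#' The matched lid \eqn{Z_{top} = \rho c} yields a pure upward-travelling
#' wave of amplitude \eqn{\rho c \omega D}; a rigid lid
#' (\eqn{Z_{top} \to \infty}) forces a pressure antinode at the lid.
#'
#' @param h Column height, m.
#' @param medium An `al_material`.
#' @param bottom_displacement Piston displacement amplitude D, m.
#' @param Z_top Lid impedance, Pa s/m (>= 1e12 or `Inf` is treated as rigid).
#' @param f Drive frequency, Hz.
#' @param loss Optional relative loss factor; the wavenumber becomes
#'   \eqn{k = (\omega/c)(1 + i\,loss)}. Default 0 (lossless).
#' @return An object of class `al_column` with complex coefficients `A`, `B`,
#'   wavenumber `k`, and the inputs.
#' @examples
#' w <- make_material("water", 1000, 1480)
#' sol <- solve_column(1.1e-3, w, 69e-9, 13e6, 660e3)
#' max_pressure(sol) / 1e6 # MPa
#' @export
solve_column <- function(h, medium, bottom_displacement, Z_top, f, loss = 0) {
  check_positive_scalar(h, "h")
  if (!inherits(medium, "al_material")) stop("'medium' must be an al_material")
  check_nonnegative_scalar(bottom_displacement, "bottom_displacement")
  if (!(Z_top > 0)) stop("'Z_top' must be > 0 (Inf allowed for rigid)")
  check_positive_scalar(f, "f")
  om <- 2 * pi * f
  rho <- medium$density
  k <- (om / medium$sound_speed) * (1 + 1i * loss)
  zfac <- if (is.infinite(Z_top)) 0 else 1i * om * rho / Z_top
  eh <- exp(1i * k * h); emh <- exp(-1i * k * h)
  M <- rbind(
    c(1i * k, -1i * k),
    c((1i * k - zfac) * eh, (-1i * k - zfac) * emh))
  det2 <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  scale2 <- abs(M[1, 1] * M[2, 2]) + abs(M[1, 2] * M[2, 1])
  if (abs(det2) < 1e-13 * scale2)
    stop("singular column system (exact lossless resonance); ",
         "supply a small 'loss' factor to regularise")
  ab <- solve(M, c(rho * om^2 * bottom_displacement, 0))
  structure(
    list(A = ab[1], B = ab[2], k = k, h = h, medium = medium,
         omega = om, Z_top = Z_top, bottom_displacement = bottom_displacement),
    class = "al_column")
}

#' Evaluate a 1D column solution
#'
#' @param sol An `al_column`.
#' @param z Heights in m (any vector within `[0, h]`).
#' @return Complex pressure amplitude(s), Pa.
#' @export
column_pressure <- function(sol, z) {
  sol$A * exp(1i * sol$k * z) + sol$B * exp(-1i * sol$k * z)
}

#' @export
print.al_column <- function(x, ...) {
  cat(sprintf(
    "<al_column> h = %g mm, f = %g kHz, Z_top = %g; max|p| = %.4g MPa\n",
    x$h * 1e3, x$omega / (2 * pi * 1e3), x$Z_top, max_pressure(x) / 1e6))
  invisible(x)
}

#' Pressure-node heights of a column solution
#'
#' Finds interior local minima of |p(z)| sampled at the requested
#' resolution, refined by three-point parabolic interpolation. Minima with
#' modulation depth below 1% of the global |p| maximum (e.g. the ripple-free
#' matched-lid case) are discarded.
#'
#' @param sol An `al_column`.
#' @param resolution Sampling step in m; must be < h/10.
#' @return Numeric vector of node heights (m), ascending; may be empty.
#' @export
node_positions <- function(sol, resolution = sol$h / 1000) {
  if (!(resolution < sol$h / 10)) stop("'resolution' must be < h/10")
  z <- seq(0, sol$h, by = resolution)
  mag <- abs(column_pressure(sol, z))
  find_profile_minima(z, mag, prominence = 0.01 * max(mag))
}

# Interior local minima of a sampled profile, parabolic-refined; a minimum
# must sit at least `prominence` below the lower of its flanking maxima.
find_profile_minima <- function(z, mag, prominence = 0) {
  n <- length(mag)
  if (n < 3) return(numeric(0))
  idx <- which(diff(sign(diff(mag))) > 0) + 1L  # strict local minima
  keep <- vapply(idx, function(i) {
    left <- max(mag[1:i]); right <- max(mag[i:n])
    min(left, right) - mag[i] >= prominence
  }, logical(1))
  idx <- idx[keep]
  vapply(idx, function(i) parabolic_refine(z[(i - 1):(i + 1)], mag[(i - 1):(i + 1)]),
         numeric(1))
}

# Vertex of the parabola through three (z, value) samples; falls back to the
# central sample for a degenerate (flat) triple.
parabolic_refine <- function(z3, v3) {
  den <- v3[1] - 2 * v3[2] + v3[3]
  if (abs(den) < .Machine$double.eps * max(abs(v3), 1)) return(z3[2])
  z3[2] - (z3[2] - z3[1]) * (v3[3] - v3[1]) / (2 * den)
}

#' Maximum pressure amplitude of a column solution
#'
#' @param sol An `al_column`.
#' @param n Number of samples over `[0, h]` used for the search.
#' @return max |p| in Pa.
#' @export
max_pressure <- function(sol, n = 20001) {
  z <- seq(0, sol$h, length.out = n)
  max(abs(column_pressure(sol, z)))
}

#' Frequency response of the driven column
#'
#' Samples max |p| over a frequency range and reports the peak.
#'
#' @param h Column height, m.
#' @param medium An `al_material`.
#' @param bottom_displacement Piston displacement amplitude, m (fixed across
#'   frequencies; a displacement-per-volt map times voltage).
#' @param Z_top Lid impedance, Pa s/m.
#' @param f_range Length-2 frequency range in Hz, within (0, 5 MHz).
#' @param n Number of frequency samples.
#' @param loss Optional loss factor passed to [solve_column()].
#' @return A data.frame with columns `f` (Hz) and `max_p` (Pa); the peak
#'   frequency is attached as attribute `"peak_f"`.
#' @export
resonance_sweep <- function(h, medium, bottom_displacement, Z_top,
                            f_range, n = 201, loss = 0) {
  stopifnot(length(f_range) == 2, all(f_range > 0), all(f_range < 5e6))
  fs <- seq(f_range[1], f_range[2], length.out = n)
  mp <- vapply(fs, function(f)
    max_pressure(solve_column(h, medium, bottom_displacement, Z_top, f, loss)),
    numeric(1))
  out <- data.frame(f = fs, max_p = mp)
  attr(out, "peak_f") <- fs[which.max(mp)]
  out
}
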