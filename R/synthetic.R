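#' Generate a spheroid population
#'
#' Draws spheroid diameters i.i.d. from a Gaussian truncated at +/- 3 sd
#' (rejection sampling), so a nominal "140 +/- 10 um" population never
#' produces unphysical sizes. Reproducible under `seed`.
#'
#' @param n Number of spheroids (>= 1).
#' @param mean_diameter Mean diameter, um.
#' @param sd_diameter SD of diameter, um (requires `mean > 3 * sd`).
#' @param density Spheroid density, kg/m^3.
#' @param seed Integer RNG seed.
#' @param compressibility Spheroid compressibility, 1/Pa.
#' @return A data.frame of class `al_population` with columns
#'   `diameter_um`, `radius_m`, `density`, `compressibility`.
#' @examples
#' pop <- gen_population(10, 140, 10, seed = 1)
#' range(pop$diameter_um)
#' @export
gen_population <- function(n, mean_diameter, sd_diameter, density = 1099,
                           seed, compressibility = 4.0e-10) {
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1")
  check_positive_scalar(mean_diameter, "mean_diameter")
  check_nonnegative_scalar(sd_diameter, "sd_diameter")
  if (mean_diameter <= 3 * sd_diameter)
    stop("'mean_diameter' must exceed 3 * sd_diameter")
  check_positive_scalar(density, "density")
  set.seed(as.integer(seed))
  d <- numeric(0)
  while (length(d) < n) {
    draw <- stats::rnorm(n, mean_diameter, sd_diameter)
    keep <- abs(draw - mean_diameter) <= 3 * sd_diameter
    d <- c(d, draw[keep])
  }
  d <- d[seq_len(n)]
  structure(
    data.frame(diameter_um = d, radius_m = d / 2 * 1e-6,
               density = density, compressibility = compressibility),
    class = c("al_population", "data.frame"))
}

#' Sedimentation artifact parameters
#'
#' Parameters of the mixture model for sedimented-height artifacts:
#' floor roughness (the cast gel bottom is not flat), stacking (spheroids
#' settling on top of one another), wall adhesion (spheroids stuck on the
#' well side walls at arbitrary height), measurement noise, and per-block
#' frame-height offsets.
#'
#' @param floor_roughness_sd SD of the half-normal floor-topography offset, um.
#' @param stacking_probability Probability a spheroid rests on another.
#' @param wall_adhesion_probability Probability a spheroid adheres to a
#'   side wall at uniform height.
#' @param measurement_noise_sd SD of measurement noise, um.
#' @param block_offset_sd SD of per-block height offsets, um.
#' @return A list of class `al_artifacts`.
#' @export
artifact_params <- function(floor_roughness_sd = 35,
                            stacking_probability = 0.25,
                            wall_adhesion_probability = 0.03,
                            measurement_noise_sd = 15,
                            block_offset_sd = 0) {
  check_nonnegative_scalar(floor_roughness_sd, "floor_roughness_sd")
  check_nonnegative_scalar(measurement_noise_sd, "measurement_noise_sd")
  check_nonnegative_scalar(block_offset_sd, "block_offset_sd")
  for (p in c(stacking_probability, wall_adhesion_probability))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]")
  structure(
    list(floor_roughness_sd = floor_roughness_sd,
         stacking_probability = stacking_probability,
         wall_adhesion_probability = wall_adhesion_probability,
         measurement_noise_sd = measurement_noise_sd,
         block_offset_sd = block_offset_sd),
    class = "al_artifacts")
}

#' Synthetic sedimented spheroid heights
#'
#' Emulates the measured centre-of-mass heights of spheroids that settled
#' to the chamber floor. Per spheroid: base height = radius + |half-normal
#' floor-roughness draw|; with `stacking_probability` the diameter of a
#' randomly drawn population member is added; with
#' `wall_adhesion_probability` the height is replaced by a uniform draw
#' over `(radius, chamber_height - radius)`; Gaussian measurement noise is
#' added and the result clamped to the physical range.
#'
#' @param pop An `al_population` from [gen_population()].
#' @param params An `al_artifacts`.
#' @param seed Integer RNG seed.
#' @param chamber_height_um Fluid height, um.
#' @param group Group label attached to the samples.
#' @param n_blocks Number of hydrogel blocks (round-robin assignment).
#' @return A data.frame of class `al_heights` with columns `group`,
#'   `block`, `diameter_um`, `height_um`.
#' @export
gen_sedimented_heights <- function(pop, params = artifact_params(), seed,
                                   chamber_height_um = 1100,
                                   group = "sedimented", n_blocks = 1) {
  if (!nrow(pop)) stop("empty population")
  stopifnot(inherits(params, "al_artifacts"))
  set.seed(as.integer(seed))
  n <- nrow(pop)
  r <- pop$diameter_um / 2
  h <- r + abs(stats::rnorm(n, 0, params$floor_roughness_sd))
  stacked <- stats::runif(n) < params$stacking_probability
  if (any(stacked))
    h[stacked] <- h[stacked] +
      pop$diameter_um[sample.int(n, sum(stacked), replace = TRUE)]
  walled <- stats::runif(n) < params$wall_adhesion_probability
  if (any(walled))
    h[walled] <- stats::runif(sum(walled), r[walled],
                              chamber_height_um - r[walled])
  block <- rep_len(seq_len(n_blocks), n)
  if (params$block_offset_sd > 0)
    h <- h + stats::rnorm(n_blocks, 0, params$block_offset_sd)[block]
  h <- h + stats::rnorm(n, 0, params$measurement_noise_sd)
  h <- pmin(pmax(h, r), chamber_height_um - r)
  structure(
    data.frame(group = group, block = block,
               diameter_um = pop$diameter_um, height_um = h),
    class = c("al_heights", "data.frame"))
}

#' Synthetic levitated spheroid heights
#'
#' Levitated spheroids collect on the pressure-node plane regardless of
#' size; residual dispersion comes from per-block frame-height
#' inhomogeneity (a Gaussian offset shared by all spheroids of one
#' hydrogel block) plus independent per-spheroid jitter. The pooled
#' distribution is Gaussian with variance
#' `block_offset_sd^2 + spheroid_jitter_sd^2` and is independent of
#' spheroid diameter.
#'
#' @param pop An `al_population`.
#' @param node_height Node-plane height, um.
#' @param block_offset_sd SD of per-block offsets, um.
#' @param spheroid_jitter_sd SD of per-spheroid jitter, um.
#' @param n_blocks Number of hydrogel blocks (>= 1, round-robin).
#' @param seed Integer RNG seed.
#' @param group Group label.
#' @param chamber_height_um Fluid height for clamping, um.
#' @return An `al_heights` data.frame (`group`, `block`, `diameter_um`,
#'   `height_um`).
#' @export
gen_levitated_heights <- function(pop, node_height, block_offset_sd = 30,
                                  spheroid_jitter_sd = 40, n_blocks = 4,
                                  seed, group = "levitated",
                                  chamber_height_um = 1100) {
  if (!nrow(pop)) stop("empty population")
  if (n_blocks < 1) stop("'n_blocks' must be >= 1")
  check_nonnegative_scalar(block_offset_sd, "block_offset_sd")
  check_nonnegative_scalar(spheroid_jitter_sd, "spheroid_jitter_sd")
  set.seed(as.integer(seed))
  n <- nrow(pop)
  block <- rep_len(seq_len(n_blocks), n)
  offsets <- stats::rnorm(n_blocks, 0, block_offset_sd)
  h <- node_height + offsets[block] + stats::rnorm(n, 0, spheroid_jitter_sd)
  r <- pop$diameter_um / 2
  h <- pmin(pmax(h, r), chamber_height_um - r)
  structure(
    data.frame(group = group, block = block,
               diameter_um = pop$diameter_um, height_um = h),
    class = c("al_heights", "data.frame"))
}

#' Named presets for the measured spheroid populations
#'
#' Frozen parameter sets emulating the five measured populations: two
#' sedimented (HepG2 with 140 um and 340 um nominal diameters) and three
#' levitated (HepG2-140, HepG2-340, HCT-140). Levitated presets use exact
#' variance addition to reach the reported pooled SDs (e.g. 30 um block
#' offset + 40 um jitter = 50 um pooled); sedimented presets were
#' calibrated once against the reported Gaussian fits and frozen.
#'
#' @param name Preset name; one of `"sedimented-HepG2-140"`,
#'   `"sedimented-HepG2-340"`, `"levitated-HepG2-140"`,
#'   `"levitated-HepG2-340"`, `"levitated-HCT-140"`. Missing: list all.
#' @return A list of preset parameters (or a named list of all presets).
#' @export
spheroid_presets <- function(name) {
  presets <- list(
    "sedimented-HepG2-140" = list(
      kind = "sedimented", mean_diameter = 140, sd_diameter = 10,
      n = 220, n_blocks = 3,
      params = artifact_params(floor_roughness_sd = 35,
                               stacking_probability = 0.25,
                               wall_adhesion_probability = 0.03,
                               measurement_noise_sd = 15)),
    "sedimented-HepG2-340" = list(
      kind = "sedimented", mean_diameter = 340, sd_diameter = 40,
      n = 76, n_blocks = 4,
      params = artifact_params(floor_roughness_sd = 40,
                               stacking_probability = 0.07,
                               wall_adhesion_probability = 0.015,
                               measurement_noise_sd = 12)),
    "levitated-HepG2-140" = list(
      kind = "levitated", mean_diameter = 140, sd_diameter = 10,
      n = 285, n_blocks = 4, node_height = 510,
      block_offset_sd = 30, spheroid_jitter_sd = 40),
    "levitated-HepG2-340" = list(
      kind = "levitated", mean_diameter = 340, sd_diameter = 40,
      n = 45, n_blocks = 3, node_height = 500,
      block_offset_sd = 48, spheroid_jitter_sd = 64),
    "levitated-HCT-140" = list(
      kind = "levitated", mean_diameter = 140, sd_diameter = 10,
      n = 155, n_blocks = 3, node_height = 475,
      block_offset_sd = 33, spheroid_jitter_sd = 44))
  if (missing(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Generate synthetic heights from a named preset
#'
#' @param name Preset name, see [spheroid_presets()].
#' @param seed Integer RNG seed.
#' @param n Optional sample-size override (default: the preset's measured n).
#' @param node_height Optional node-height override, um (e.g. a simulated
#'   node height instead of the preset's measured mean).
#' @return An `al_heights` data.frame.
#' @examples
#' h <- generate_preset("levitated-HepG2-140", seed = 7)
#' mean(h$height_um)
#' @export
generate_preset <- function(name, seed, n = NULL, node_height = NULL) {
  ps <- spheroid_presets(name)
  n <- n %||% ps$n
  pop <- gen_population(n, ps$mean_diameter, ps$sd_diameter, seed = seed)
  if (ps$kind == "sedimented") {
    gen_sedimented_heights(pop, ps$params, seed = seed + 1L, group = name,
                           n_blocks = ps$n_blocks)
  } else {
    gen_levitated_heights(pop, node_height %||% ps$node_height,
                          ps$block_offset_sd, ps$spheroid_jitter_sd,
                          ps$n_blocks, seed = seed + 1L, group = name)
  }
}
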