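#' Run the full in-silico levitation experiment
#'
#' Orchestrates the pipeline mirroring the physical workflow: build the
#' device model, solve the chamber pressure field, evaluate the Gor'kov
#' force on the reference spheroid, trace a batch of spheroids from floor
#' starts to their levitation heights, generate a synthetic measured
#' population around the simulated node height, and emit the alignment
#' statistics report. All stage outputs are written under `out_dir`, and a
#' JSON manifest (config hash, seed, file list, versions) is written last.
#'
#' One global `seed` is expanded into per-stage seeds (`seed + stage
#' counter`) so the generator stages can be re-run independently yet
#' reproducibly.
#'
#' @param config Path to a config file ([read_config()]) or a list as
#'   returned by it; `NULL` uses the model A defaults.
#' @param seed Integer seed for the synthetic-measurement stages.
#' @param out_dir Output directory (created if missing).
#' @param resolution Solver resolution, m.
#' @param n_trajectories Number of floor-start spheroids to trace.
#' @param n_synthetic Number of synthetic measured spheroids.
#' @param traj_t_end Trajectory horizon, s (levitation to the node takes
#'   well under a second; lateral creep to the trap centre is not needed
#'   for the height report).
#' @param traj_step_limit Maximum displacement per integrator step, m.
#' @return The manifest (list), invisibly; side effect: files in `out_dir`.
#' @export
simulate_full_experiment <- function(config = NULL, seed = 1,
                                     out_dir = tempfile("acoustolev_run_"),
                                     resolution = c(100e-6, 100e-6, 50e-6),
                                     n_trajectories = 5,
                                     n_synthetic = 285,
                                     traj_t_end = 3,
                                     traj_step_limit = 25e-6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (is.null(config)) c(model_a_config(),
                                list(particle = particle_spec(75e-6, 1099)))
         else if (is.character(config)) read_config(config)
         else config
  cfg_hash <- config_hash(cfg)
  outputs <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    res
  }

  fld <- stage("solve", solve_pressure(cfg$chamber, cfg$map, resolution))
  outputs$field_probe <- file.path(out_dir, "center_column.csv")
  utils::write.csv(probe_column(fld, 0, 0), outputs$field_probe,
                   row.names = FALSE)
  outputs$field_vtk <- file.path(out_dir, "field.vtk")

  force <- stage("force", radiation_force(gorkov_potential(fld, cfg$particle)))
  write_vtk_field(fld, outputs$field_vtk, force = force)

  node_z <- stage("node", node_plane(fld, 0, 0))
  eq_z <- stage("equilibrium",
                equilibrium_height(cfg$particle, force, 0, 0))

  starts <- cbind(
    x = seq(-0.8e-3, 0.8e-3, length.out = n_trajectories),
    y = rep(0, n_trajectories),
    z = rep(cfg$particle$radius, n_trajectories))
  trajs <- stage("trace", apply(starts, 1, function(s)
    simulate_trajectory(cfg$particle, s, force, cfg$chamber$fluid,
                        t_end = traj_t_end, step_limit = traj_step_limit)))
  traj_tab <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    cbind(id = i, trajs[[i]]$path)
  }))
  outputs$trajectories <- file.path(out_dir, "trajectories.csv")
  utils::write.csv(traj_tab, outputs$trajectories, row.names = FALSE)

  node_um <- node_z * 1e6
  synth <- stage("synth", rbind(
    generate_preset("levitated-HepG2-140", seed = seed + 10L,
                    n = n_synthetic, node_height = node_um),
    generate_preset("sedimented-HepG2-140", seed = seed + 20L)))
  outputs$synthetic <- file.path(out_dir, "synthetic_heights.csv")
  utils::write.csv(synth, outputs$synthetic, row.names = FALSE)

  report <- stage("stats", group_report(synth))
  outputs$stats <- file.path(out_dir, "stats.csv")
  utils::write.csv(cbind(report$stats,
                         node_height_um = node_um,
                         equilibrium_height_um = eq_z * 1e6),
                   outputs$stats, row.names = FALSE)

  manifest <- list(
    config_hash = cfg_hash,
    seed = seed,
    resolution = resolution,
    node_height_um = node_um,
    equilibrium_height_um = eq_z * 1e6,
    max_pressure_MPa = max(abs(fld$p)) / 1e6,
    outputs = lapply(outputs, normalizePath),
    versions = list(acoustolev = as.character(utils::packageVersion("acoustolev")),
                    R = R.version.string))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Deterministic hash of a configuration: md5 of its deparsed numeric content.
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(list(chamber = cfg$chamber[c("lateral_size", "fluid_height",
                                    "top_impedance", "side_impedance")],
            fluid = cfg$chamber$fluid[c("density", "sound_speed")],
            map = cfg$map[c("units", "epoxy", "unit_size", "pitch",
                            "drive_voltage", "frequency")],
            particle = unclass(cfg$particle)),
       file = tmp)
  unname(tools::md5sum(tmp))
}

#' Alignment statistics from a heights CSV
#'
#' Stats-only entry point: reads a CSV of measured or synthetic heights
#' and produces the same group report as the full pipeline.
#'
#' @param path CSV with at least the group and height columns.
#' @param group_col,height_col Column names.
#' @return An `al_report`.
#' @export
stats_from_csv <- function(path, group_col = "group",
                           height_col = "height_um") {
  tab <- utils::read.csv(path)
  if (!all(c(group_col, height_col) %in% names(tab)))
    stop("CSV must contain columns '", group_col, "' and '", height_col, "'")
  df <- data.frame(group = tab[[group_col]], height_um = tab[[height_col]])
  group_report(df)
}
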