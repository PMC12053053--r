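w <- make_material("water", 1000, 1480)

test_that("net force reproduces hand-computed weight and buoyancy values", {
  sp <- ref_particle()  # a = 75 um, rho = 1099
  # buoyancy-corrected weight: V * (rho_m - rho_p) * g = 1.72 nN downward
  f <- net_force(sp, c(0, 0, 5e-4), NULL, w)
  expect_equal(f[1:2], c(0, 0))
  expect_equal(f[3], -(4 / 3) * pi * (75e-6)^3 * 99 * 9.81, tolerance = 1e-12)
  expect_equal(f[3], -1.716e-9, tolerance = 1e-3)
  # plain weight without the Archimedes term: ~19 nN
  f0 <- net_force(sp, c(0, 0, 5e-4), NULL, w, buoyancy = FALSE)
  expect_equal(f0[3], -sp$density * sp$volume * 9.81, tolerance = 1e-12)
  # density-matched particle in no field: exactly zero
  neutral <- particle_spec(75e-6, 1000)
  expect_equal(net_force(neutral, c(0, 0, 5e-4), NULL, w), c(0, 0, 0))
})

test_that("free sedimentation falls at the Stokes terminal speed", {
  sp <- ref_particle()
  ch <- model_a_config()$chamber
  tr <- simulate_trajectory(sp, c(0, 0, 9e-4), NULL, w, viscosity = 1e-3,
                            t_end = 2, chamber = ch)
  expect_true(tr$converged)
  expect_equal(tr$terminal_position[3], sp$radius)  # resting on the floor
  mid <- tr$path[tr$path$z < 7e-4 & tr$path$z > 3e-4, ]
  v_num <- abs(diff(range(mid$z)) / diff(range(mid$t)))
  v_stokes <- 2 * 99 * 9.81 * (75e-6)^2 / (9 * 1e-3)  # ~1.21 mm/s
  expect_equal(v_num, v_stokes, tolerance = 1e-3)
})

test_that("floor-started spheroids levitate to the node plane", {
  sp <- ref_particle()
  force <- cached_force("A")
  tr <- simulate_trajectory(sp, c(0.4e-3, 0, sp$radius), force, w,
                            t_end = 2, step_limit = 25e-6)
  node <- node_plane(cached_field("A"), tr$terminal_position[1],
                     tr$terminal_position[2])
  expect_lt(abs(tr$terminal_position[3] - node), 20e-6)
})

test_that("overdamped descent is monotone in the total potential", {
  sp <- ref_particle()
  force <- cached_force("A")
  tr <- simulate_trajectory(sp, c(0.6e-3, 0.2e-3, sp$radius), force, w,
                            t_end = 1.5, step_limit = 25e-6)
  pth <- tr$path
  U_tot <- vapply(seq_len(nrow(pth)), function(i)
    acoustolev:::gorkov_at(force, c(pth$x[i], pth$y[i], pth$z[i])) +
      (sp$density - w$density) * sp$volume * 9.81 * pth$z[i],
    numeric(1))
  allowance <- 1e-6 * diff(range(U_tot))
  expect_true(all(diff(U_tot) <= allowance))
})

test_that("equilibrium height is independent of spheroid size and viscosity", {
  small <- particle_spec(35e-6, 1099)
  large <- particle_spec(85e-6, 1099)
  fs <- radiation_force(gorkov_potential(cached_field("A"), small))
  fl <- radiation_force(gorkov_potential(cached_field("A"), large))
  zs <- equilibrium_height(small, fs, 0, 0)
  zl <- equilibrium_height(large, fl, 0, 0)
  expect_lt(abs(zs - zl), 25e-6)
  # viscosity affects kinetics only: trajectories end at the same height
  sp <- ref_particle()
  force <- cached_force("A")
  t1 <- simulate_trajectory(sp, c(0.2e-3, 0, 4e-4), force, w,
                            viscosity = 0.8e-3, t_end = 1.5,
                            step_limit = 25e-6)
  t2 <- simulate_trajectory(sp, c(0.2e-3, 0, 4e-4), force, w,
                            viscosity = 1.6e-3, t_end = 3,
                            step_limit = 25e-6)
  # terminal points are discrete potential minima; agreement is limited by
  # the interpolation cell (dz = 50 um), not by viscosity
  expect_lt(abs(t1$terminal_position[3] - t2$terminal_position[3]), 10e-6)
})

test_that("equilibrium sits at the trap for neutral buoyancy, errors when weak", {
  # neutrally buoyant: equilibrium is exactly the zero of the radiation force
  neutral <- particle_spec(75e-6, 1000, compressibility = 3.5e-10)
  fn <- radiation_force(gorkov_potential(cached_field("A"), neutral))
  z_eq <- equilibrium_height(neutral, fn, 0, 0)
  fz <- net_force(neutral, c(0, 0, z_eq), fn, w)[3]
  expect_lt(abs(fz), 1e-9)  # bisection window 0.1 um times the trap stiffness
  # heavy particle beats a 1000x weakened field: no bracketing interval
  sp <- ref_particle()
  weak <- cached_force("A")
  weak$Fx <- weak$Fx / 1000; weak$Fy <- weak$Fy / 1000
  weak$Fz <- weak$Fz / 1000
  expect_error(equilibrium_height(sp, weak, 0, 0), "levitatable")
})

test_that("trap layout: one trap per unit, same positions for models A and B", {
  sp <- ref_particle()
  tpA <- trap_positions(cached_force("A"), sp)
  tpB <- trap_positions(cached_force("B"), sp)
  expect_equal(nrow(tpA), 9)
  expect_equal(nrow(tpB), 9)
  ctr <- expand.grid(x = c(-2.4e-3, 0, 2.4e-3), y = c(-2.4e-3, 0, 2.4e-3))
  half <- 1e-3
  for (tp in list(tpA, tpB)) {
    hit <- mapply(function(x, y)
      any(abs(ctr$x - x) <= half & abs(ctr$y - y) <= half), tp$x, tp$y)
    expect_true(all(hit))
  }
  # same lateral layout in both models, within one grid cell
  oA <- order(tpA$x, tpA$y); oB <- order(tpB$x, tpB$y)
  expect_true(all(abs(tpA$x[oA] - tpB$x[oB]) <= 1.5e-4))
  expect_true(all(abs(tpA$y[oA] - tpB$y[oB]) <= 1.5e-4))
})

test_that("laterally uniform field reports a degenerate (trap-free) node plane", {
  ch <- chamber_config(lateral_size = c(2e-3, 2e-3), fluid = w,
                       side_impedance = Inf)
  map <- transducer_map(units = matrix(1.15e-9, 3, 3), epoxy = 1.15e-9,
                        unit_size = 0.5e-3, pitch = 0.6e-3)
  fld <- solve_pressure(ch, map, resolution = c(200e-6, 200e-6, 25e-6))
  force <- radiation_force(gorkov_potential(fld, ref_particle()))
  tp <- trap_positions(force, ref_particle())
  expect_equal(nrow(tp), 0)
  expect_true(attr(tp, "degenerate"))
})
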