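test_that("laterally uniform 3D solve matches the 1D closed form to <1% L2", {
  # all regions driven equally + rigid (mirror-like) lateral walls = 1D physics
  w <- make_material("water", 1000, 1480)
  ch <- chamber_config(lateral_size = c(2e-3, 2e-3), fluid = w,
                       side_impedance = Inf)
  map <- transducer_map(units = matrix(1.15e-9, 3, 3), epoxy = 1.15e-9,
                        unit_size = 0.5e-3, pitch = 0.6e-3)
  fld <- solve_pressure(ch, map, resolution = c(200e-6, 200e-6, 20e-6))
  sol <- solve_column(ch$fluid_height, w, 69e-9, ch$top_impedance,
                      map$frequency)
  p1d <- column_pressure(sol, fld$z)
  for (ix in seq_along(fld$x)) for (iy in seq_along(fld$y)) {
    col <- fld$p[ix, iy, ]
    expect_lt(sqrt(sum(abs(col - p1d)^2) / sum(abs(p1d)^2)), 0.01)
  }
})

test_that("solved field satisfies the interior Helmholtz equation", {
  expect_lt(helmholtz_residual(cached_field("A")), 1e-10)
  expect_lt(helmholtz_residual(cached_field("B")), 1e-10)
})

test_that("field scales linearly with drive voltage", {
  cfg <- model_a_config()
  map2 <- cfg$map
  map2$drive_voltage <- 2 * map2$drive_voltage
  f1 <- solve_pressure(cfg$chamber, cfg$map, resolution = coarse_res())
  f2 <- solve_pressure(cfg$chamber, map2, resolution = coarse_res())
  expect_lt(max(abs(f2$p - 2 * f1$p)) / max(abs(f2$p)), 1e-10)
  expect_lt(max(abs(f2$vz - 2 * f1$vz)) / max(abs(f2$vz)), 1e-10)
})

test_that("mirror reconstruction restores the full symmetric chamber", {
  fld <- cached_field("A")
  full <- reconstruct_full(fld)
  expect_false(any(full$quarter))
  expect_length(full$x, 2 * length(fld$x) - 1)
  # even parity of p, odd parity of the normal velocity components
  expect_equal(full$p[1, , ], full$p[length(full$x), , ])
  expect_equal(full$vx, -mirror_flip(full$vx, 1))
  expect_equal(full$vy, -mirror_flip(full$vy, 2))
  expect_equal(full$p, mirror_flip(full$p, 1))
  expect_equal(full$p, mirror_flip(full$p, 2))
})

test_that("matched walls preclude resonant buildup", {
  w <- make_material("water", 1000, 1480)
  ch <- chamber_config(top_impedance = w$impedance,
                       side_impedance = w$impedance, fluid = w)
  map <- model_a_config()$map
  fld <- solve_pressure(ch, map, resolution = coarse_res())
  matched_1d <- w$impedance * 2 * pi * map$frequency * 69e-9
  expect_lt(max(abs(fld$p)), 2 * matched_1d)
})

test_that("node extraction: 1D limits and absence on monotone columns", {
  w <- make_material("water", 1000, 1480)
  h <- 1.1e-3; f <- 660e3
  lambda <- w$sound_speed / f
  ch_rigid <- chamber_config(lateral_size = c(2e-3, 2e-3), fluid = w,
                             top_impedance = Inf, side_impedance = Inf)
  map <- transducer_map(units = matrix(1e-9, 3, 3), epoxy = 1e-9,
                        unit_size = 0.5e-3, pitch = 0.6e-3, frequency = f)
  fld <- solve_pressure(ch_rigid, map, resolution = c(200e-6, 200e-6, 10e-6))
  expect_equal(node_plane(fld, 0, 0), h - lambda / 4, tolerance = 2e-3)
  # matched lid: no standing-wave minimum anywhere on the column
  ch_match <- chamber_config(lateral_size = c(2e-3, 2e-3), fluid = w,
                             top_impedance = w$impedance, side_impedance = Inf)
  fld2 <- solve_pressure(ch_match, map, resolution = c(200e-6, 200e-6, 20e-6))
  expect_true(is.na(node_plane(fld2, 0, 0)))
})

test_that("resolution bounds are enforced with an informative message", {
  cfg <- model_a_config()
  expect_error(solve_pressure(cfg$chamber, cfg$map,
                              resolution = c(100e-6, 100e-6, 200e-6)),
               "lambda/15")
  expect_error(solve_pressure(cfg$chamber, cfg$map,
                              resolution = c(300e-6, 100e-6, 50e-6)),
               "lambda/10")
})

test_that("grid refinement converges on node height and max pressure", {
  cfg <- model_a_config()
  st <- convergence_study(cfg$chamber, cfg$map, list(
    c(200e-6, 200e-6, 100e-6),
    c(200e-6, 200e-6, 50e-6),
    c(200e-6, 200e-6, 25e-6)))
  ch <- st$rel_change_node_z[-1]
  expect_lt(ch[2], ch[1])           # second-order-ish shrinkage
  expect_lt(st$rel_change_max_p[3], 0.05)
  # identical resolutions give zero change rows
  st0 <- convergence_study(cfg$chamber, cfg$map, list(
    coarse_res(), coarse_res(), coarse_res()))
  expect_equal(st0$rel_change_max_p[-1], c(0, 0))
})

test_that("model A node heights are near-identical above every unit", {
  fld <- cached_field("A")
  nodes <- c(node_plane(fld, 0, 0),
             node_plane(fld, 2.4e-3, 0),
             node_plane(fld, 2.4e-3, 2.4e-3))
  expect_true(all(is.finite(nodes)))
  expect_lt(diff(range(nodes)), 0.10 * fld$chamber$fluid_height)
})
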