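# Control-volume theory: screening numbers, spectral wall pressure,
# wall-integral force recovery, aperture behaviour, compressible delay.

test_that("compactness number and acoustic delay reproduce their identities", {
  expect_equal(afp_number(0.41, 18, 340), 0.41 * 18 / 340, tolerance = 1e-12)
  expect_lte(afp_number(0.41, 18, 340), 0.022)
  expect_identical(afp_number(0.5, 0, 340), 0)
  expect_equal(afp_number(0.82, 18, 340), 2 * afp_number(0.41, 18, 340))
  expect_equal(acoustic_delay(0.41, 340) * 1000, 1.206, tolerance = 1e-3)
  expect_identical(acoustic_delay(0, 340), 0)
  # delay * f == compactness number, identically
  set.seed(42)
  for (i in 1:10) {
    L <- runif(1, 0.1, 2); f <- runif(1, 0, 50); cc <- runif(1, 100, 1500)
    expect_equal(acoustic_delay(L, cc) * f, afp_number(L, f, cc), tolerance = 1e-12)
  }
  expect_error(afp_number(-1, 18, 340), "positive")
  expect_error(acoustic_delay(0.41, 0), "positive")
})

test_that("Reynolds number screening matches the working-condition value", {
  air <- fluid_properties() # nu = 1.48e-5
  expect_equal(reynolds_number(0.95, 0.42, air), 27000, tolerance = 0.01)
  expect_identical(reynolds_number(0, 0.42, air), 0)
  expect_equal(reynolds_number(1.9, 0.42, air), 2 * reynolds_number(0.95, 0.42, air))
})

test_that("Blasius friction matches an independent similarity-ODE integration", {
  air25 <- standard_air(25)
  expect_identical(blasius_shear_force(0, 0.42, 0.525, air25), 0)
  # drag ~ U^(3/2): quadrupling U multiplies the force by 8
  expect_equal(blasius_shear_force(4 * 0.95, 0.42, 0.525, air25),
               8 * blasius_shear_force(0.95, 0.42, 0.525, air25),
               tolerance = 1e-10)
  skip_if_not_installed("deSolve")
  fpp0 <- blasius_shoot_fpp0()
  expect_equal(4 * fpp0, 1.328, tolerance = 1e-3) # the friction-law constant
  U <- 0.95; Lp <- 0.42; Wp <- 0.525
  drag_ode <- 2 * fpp0 * air25$density * U^2 *
    sqrt(air25$kinematic_viscosity * Lp / U) * Wp
  expect_equal(blasius_shear_force(U, Lp, Wp, air25), drag_ode, tolerance = 1e-3)
  # shear subordination: below 1% of a 1 N reference force
  expect_lt(blasius_shear_force(U, Lp, Wp, air25), 0.01 * 1)
})

test_that("wall pressure of a centred vertical force has the expected symmetry", {
  geom <- box_geometry()
  ctr <- c(geom$Lx, geom$Ly, geom$Lz) / 2
  fld0 <- wall_pressure_point_force(geom, point_forcing(ctr, c(0, 0, 0)),
                                    fluid_properties(), n_modes = 16,
                                    grid_resolution = 16)
  for (w in fld0$walls) expect_equal(max(abs(w$p)), 0)
  fld <- wall_pressure_point_force(geom, point_forcing(ctr, c(0, 0, 1)),
                                   fluid_properties(), n_modes = 32,
                                   grid_resolution = 32)
  # mirror antisymmetry between top and bottom walls
  expect_equal(fld$walls$top$p, -fld$walls$bottom$p, tolerance = 1e-10)
  # side walls carry no vertical component by construction of their normals
  F <- integrate_wall_force(fld, geom)
  expect_equal(F[1], 0, tolerance = 1e-10)
  expect_equal(F[2], 0, tolerance = 1e-10)
  expect_error(wall_pressure_point_force(geom,
                                         point_forcing(c(-0.1, 0.2, 0.2), c(0, 0, 1)),
                                         fluid_properties()),
               "inside")
})

test_that("spectral wall pressure agrees with the method-of-images series", {
  geom <- box_geometry()
  L <- c(geom$Lx, geom$Ly, geom$Lz)
  pos <- c(0.5 * L[1], 0.5 * L[2], 0.08) # near the bottom wall
  Fvec <- c(0, 0, 1)
  fld <- wall_pressure_point_force(geom, point_forcing(pos, Fvec),
                                   fluid_properties(), n_modes = 64,
                                   grid_resolution = 32, source_width = 0.01)
  bw <- fld$walls$bottom
  pts <- cbind(rep(bw$u, times = length(bw$v)), rep(bw$v, each = length(bw$u)), 0)
  # the body force on the fluid is the reaction -F
  p_img <- image_series_pressure(pts, pos, -Fvec, L, sigma = 0.01, n_shells = 5)
  p_spec <- as.vector(bw$p)
  p_spec <- p_spec - mean(p_spec)
  p_img <- p_img - mean(p_img)
  rel_rms <- sqrt(mean((p_spec - p_img)^2)) / sqrt(mean(p_img^2))
  expect_lt(rel_rms, 0.01)
})

test_that("a uniform pressure integrates to the zero force vector", {
  geom <- box_geometry()
  ctr <- c(geom$Lx, geom$Ly, geom$Lz) / 2
  fld <- suppressWarnings(
    wall_pressure_point_force(geom, point_forcing(ctr, c(0, 0, 1)),
                              fluid_properties(), n_modes = 8,
                              grid_resolution = 16))
  for (w in names(fld$walls)) fld$walls[[w]]$p[] <- 101325
  expect_equal(integrate_wall_force(fld, geom), c(0, 0, 0), tolerance = 1e-9)
})

test_that("wall integration recovers randomized interior forces to < 1e-3", {
  geom <- box_geometry()
  L <- c(geom$Lx, geom$Ly, geom$Lz)
  air <- fluid_properties()
  set.seed(7)
  for (i in 1:20) {
    pos <- L * runif(3, 0.2, 0.8)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    fld <- wall_pressure_point_force(geom, point_forcing(pos, dir), air)
    err <- max(abs(integrate_wall_force(fld, geom) - dir))
    expect_lt(err, 1e-3)
  }
})

test_that("force recovery converges monotonically in mode count", {
  geom <- box_geometry()
  frc <- point_forcing(c(0.20, 0.28, 0.17), c(0.3, -0.2, 0.9))
  errs <- vapply(c(8, 16, 32, 48), function(K) {
    fld <- suppressWarnings(
      wall_pressure_point_force(geom, frc, fluid_properties(), n_modes = K))
    max(abs(integrate_wall_force(fld, geom) - frc$amplitude))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[length(errs)], 1e-3)
})

test_that("an aperture in a vertical wall leaves the vertical force unchanged", {
  ctr <- c(0.26, 0.21)
  frc <- point_forcing(c(0.2, 0.25, 0.22), c(0.4, 0.3, 1))
  air <- fluid_properties()
  g0 <- box_geometry()
  F0 <- integrate_wall_force(wall_pressure_point_force(g0, frc, air,
                                                       n_modes = 32,
                                                       grid_resolution = 32), g0)
  for (d in c(0.100, 0.175, 0.250)) {
    g <- box_geometry(aperture = list(wall = "front", center = ctr, diameter = d))
    fld <- wall_pressure_point_force(g, frc, air, n_modes = 32, grid_resolution = 32)
    Fd <- integrate_wall_force(fld, g)
    # the front wall normal has no vertical component: exact insensitivity
    # (machine precision; only the gauge constant is re-rounded)
    expect_equal(Fd[3], F0[3], tolerance = 1e-12)
    # ... while the horizontal component normal to the holed wall does change
    expect_false(isTRUE(all.equal(Fd[2], F0[2], tolerance = 1e-9)))
  }
  expect_equal(aperture_area_ratio(
    box_geometry(aperture = list(wall = "front", center = ctr, diameter = 0.25))),
    0.223, tolerance = 2e-3)
  expect_error(box_geometry(aperture = list(wall = "front", center = c(0.02, 0.02),
                                            diameter = 0.25)),
               "within its wall")
})

test_that("compressible wall force is delayed by sound transit, vanishing as c grows", {
  frc <- point_forcing(c(0.2, 0.2, 0.205), c(0, 0, 1),
                       waveform = "sinusoid", frequency = 18)
  geom <- box_geometry(0.41, 0.41, 0.41)
  fast <- compressible_delay_demo(geom, frc, fluid_properties(sound_speed = 1e5),
                                  duration = 0.4)
  expect_lt(abs(fast$delay_fraction), 1e-4)
  expect_lt(abs(fast$arrival_fraction), 1e-3)
  # delay fraction grows monotonically across a log-spaced compactness sweep
  afpn <- 10^seq(-3, -1, length.out = 5)
  fracs <- vapply(18 * 0.41 / afpn, function(ci) {
    compressible_delay_demo(geom, frc, fluid_properties(sound_speed = ci),
                            duration = 0.4)$arrival_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
  # working conditions: arrival fraction of the order of the compactness number
  d <- compressible_delay_demo(geom, frc, fluid_properties(), duration = 0.4)
  expect_gt(d$arrival_fraction, 0.2 * d$afp_number)
  expect_lt(d$arrival_fraction, 2 * d$afp_number)
  expect_false(d$resonance_flag)
  # forcing within 1% of the first vertical acoustic mode raises the flag
  f1 <- 340 / (2 * 0.41)
  frc_res <- point_forcing(c(0.2, 0.2, 0.205), c(0, 0, 1),
                           waveform = "sinusoid", frequency = f1 * 1.004)
  expect_true(compressible_delay_demo(geom, frc_res, fluid_properties(),
                                      duration = 0.05)$resonance_flag)
})

test_that("platform pressure sensitivity follows from resolution over wall area", {
  expect_equal(pressure_sensitivity(2e-3, box_geometry()),
               2e-3 / (0.525 * 0.452), tolerance = 1e-12)
})
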