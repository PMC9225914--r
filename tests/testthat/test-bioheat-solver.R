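test_that("conduction operator annihilates constant fields and the perfusion
          sink vanishes at blood temperature", {
  block <- default_tissue_block()
  grid <- build_grid(block, fast_settings())
  op <- assemble_operator(block, grid, bottom = "insulated")
  N <- length(op$M)
  expect_lt(max(abs(op$C %*% rep(1, N))), 1e-10)
  expect_true(Matrix::isSymmetric(op$C))
  # residual of the full linear operator at T = T_b equals the metabolic
  # source plus nothing: perfusion term exactly cancels
  Tb <- block$blood$temperature
  resid <- as.vector(op$C %*% rep(Tb, N)) + op$P * Tb - op$P * Tb
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("two-layer steady column reproduces the piecewise-linear slab
          solution with interface flux continuity", {
  k1 <- 0.49; k2 <- 0.21; q0 <- 200
  block <- tissue_block(
    list(tissue_layer("top", 0.010, 911, 2348, k2),
         tissue_layer("bottom", 0.015, 1090, 3421, k1)),
    lateral_radius = 0.05, core_temperature = 37)
  stg <- solver_settings(base_dz = 5e-4, skin_dz = 5e-4, base_dr = 5e-3,
                         refine_dr = 5e-3, surface = "flux",
                         surface_flux = q0)
  ctx <- moxitherm:::solver_context(
    scenario_config(block = block, duration_s = 1), stg)
  f <- moxitherm:::steady_field(ctx)
  oracle <- analytic_problem("two_slab_steady", k1 = k1, L1 = 0.015,
                             k2 = k2, L2 = 0.010, T_bottom = 37, q_top = q0)
  z <- ctx$grid$z_c
  expect_equal(f$values[1, ], oracle$evaluate(z), tolerance = 5e-3)
  # surface temperature reconstruction hits the analytic surface value
  expect_equal(f$surface[1], oracle$evaluate(0.025), tolerance = 5e-3)
  # interface flux continuity: k dT/dz equal on both sides of z = 15 mm
  below <- z < 0.015; above <- z > 0.015
  g1 <- k1 * diff(f$values[1, below]) / diff(z[below])
  g2 <- k2 * diff(f$values[1, above]) / diff(z[above])
  expect_equal(mean(g1), mean(g2), tolerance = 1e-6)
  expect_equal(mean(g1), q0, tolerance = 1e-6)
})

test_that("uniform insulated field without sources is a fixed point of the
          step and enthalpy is conserved to 1e-8 per step", {
  block <- uniform_block()
  stg <- fast_settings(bottom = "insulated", surface = "insulated")
  sc <- scenario_config(block = block, duration_s = 10)
  ctx <- moxitherm:::solver_context(sc, stg)
  f <- moxitherm:::new_field(matrix(36, ctx$op$nr, ctx$op$nz), 0, ctx$grid)
  f1 <- step(f, 1, sc, stg)
  expect_equal(f1$values, f$values, tolerance = 1e-12)

  # non-uniform start: total enthalpy sum(M * T) invariant step by step
  set.seed(5)
  vals <- matrix(36 + rnorm(length(ctx$op$M)), ctx$op$nr, ctx$op$nz)
  f <- moxitherm:::new_field(vals, 0, ctx$grid)
  H0 <- sum(ctx$op$M * as.vector(vals))
  for (s in 1:5) {
    f <- step(f, 1, sc, stg)
    H <- sum(ctx$op$M * as.vector(f$values))
    expect_equal(H, H0, tolerance = 1e-8)
  }
})

test_that("perfusion relaxation matches the exponential closed form", {
  omega <- 0.7; qm <- 420
  block <- uniform_block(k = 0.49, rho = 1090, cp = 3421,
                         omega = omega, qm = qm)
  oracle <- analytic_problem("perfusion_relaxation", T0 = 30, T_b = 37,
                             q_m = qm, omega_b = omega, rho = 1090,
                             c = 3421)
  stg <- fast_settings(dt = 1, theta = 0.5, bottom = "insulated",
                       surface = "insulated")
  sc <- scenario_config(block = block, duration_s = 300)
  ctx <- moxitherm:::solver_context(sc, stg)
  f <- moxitherm:::new_field(matrix(30, ctx$op$nr, ctx$op$nz), 0, ctx$grid)
  t <- 0
  for (s in 1:60) { f <- step(f, 5, sc, stg); t <- t + 5 }
  exact <- oracle$evaluate(t = t)
  expect_equal(mean(f$values), exact, tolerance = 5e-3)
  # uniform stays uniform, relaxing monotonically toward T_b + qm/(w Cb)
  expect_lt(diff(range(f$values)), 1e-9)
  expect_lt(mean(f$values), oracle$params$T_b + qm / (omega * 3617))
})

test_that("constant-flux surface heating matches the semi-infinite
          conduction solution within 2%", {
  q0 <- 1000
  block <- uniform_block(thickness = 0.05, radius = 0.06)
  oracle <- analytic_problem("semi_infinite_flux", q0 = q0, k = 0.37,
                             rho = 1109, c = 3391)
  stg <- solver_settings(dt = 0.25, base_dr = 1e-2, refine_dr = 5e-3,
                         base_dz = 2e-4, skin_dz = 2e-4,
                         surface = "flux", surface_flux = q0,
                         record_dt = 30)
  sc <- scenario_config(block = block, duration_s = 40,
                        ambient_temperature = 36)
  sc$block$initial_surface_temperature <- NA_real_
  ctx <- moxitherm:::solver_context(sc, stg)
  f <- moxitherm:::new_field(matrix(36, ctx$op$nr, ctx$op$nz), 0, ctx$grid)
  t <- 0
  for (tt in c(20, 40)) {
    while (t < tt - 1e-9) { f <- step(f, 0.25, sc, stg); t <- t + 0.25 }
    rise <- f$surface[1] - 36
    expect_equal(rise, oracle$evaluate(0, t), tolerance = 0.02)
    # subsurface decay profile also tracks the closed form
    z <- 0.05 - moxitherm:::axis_probe(f$values, f$surface, ctx, 0.05 - 2e-3)
    expect_equal(moxitherm:::axis_probe(f$values, f$surface, ctx,
                                        0.05 - 2e-3) - 36,
                 oracle$evaluate(2e-3, t), tolerance = 0.03)
  }
})

test_that("resting state honours the bottom Dirichlet condition and hits the
          34.3 C disk average of the validation scenario", {
  f <- initial_state(validation_condition(), fast_settings())
  expect_equal(disk_average(f), 34.3, tolerance = 0.1 / 34.3)
  expect_equal(max(abs(f$values[, 1] - 37)), 0, tolerance = 0.05)
  # surface is cooler than the core at rest
  expect_lt(f$surface[1], 37)
})

test_that("resting state with ambient exchange switched off is the uniform
          perfusion/metabolism equilibrium", {
  omega <- 5; qm <- 2000
  block <- uniform_block(omega = omega, qm = qm)
  sc <- scenario_config(block = block, duration_s = 1)
  stg <- fast_settings(surface = "insulated")
  f <- initial_state(sc, stg, tune = "never")
  # far from the Dirichlet bottom the field sits at T_b + qm/(omega Cb)
  expect_equal(max(f$values), 37 + qm / (omega * 3617), tolerance = 1e-4)
})

test_that("zero-duration run returns the resting probes and disk_average
          reduces correctly on analytic surface fields", {
  sc <- validation_condition()
  sc$duration_s <- 1e-3  # effectively zero-duration
  stg <- fast_settings()
  r <- run_simulation(sc, stg, tune_initial = "never")
  f0 <- initial_state(sc, stg, tune = "never")
  expect_equal(r$disk_average_series$temp_C[1], disk_average(f0),
               tolerance = 1e-6)
  # the interior field is unchanged by an infinitesimal exposure (the
  # reconstructed surface skin responds instantly to the switched-on flux)
  expect_equal(r$final_field$values, f0$values, tolerance = 1e-4)

  # uniform surface: disk average equals the value
  g <- f0$grid
  fu <- moxitherm:::new_field(matrix(40, g$nr, g$nz), 0, g,
                              Ts = rep(40, g$nr))
  expect_equal(disk_average(fu), 40)
  # linear-in-r surface, T = a + b r: area-weighted mean = a + (2/3) b R
  a <- 40; b <- -100
  fl <- moxitherm:::new_field(matrix(40, g$nr, g$nz), 0, g,
                              Ts = a + b * g$r_c)
  R <- 5e-3
  # midpoint-rule annulus weights against the exact integral
  expect_equal(disk_average(fl, R), a + 2 / 3 * b * R, tolerance = 1e-4)
  # shrinking disk converges to the moxibustion-point value
  expect_equal(disk_average(fl, 2.5e-4), a + b * g$r_c[1], tolerance = 1e-6)
  expect_error(disk_average(fl, 1), "radius")
})

test_that("heated field respects the maximum principle bounds", {
  sc <- standard_condition()
  stg <- fast_settings()
  r <- run_simulation(sc, stg)
  vals <- r$final_field$values
  f0 <- initial_state(sc, stg)
  # never below the coldest of (resting field, ambient), never above the
  # radiative-equilibrium temperature of the peak source
  expect_gte(min(vals), min(min(f0$values), sc$ambient_temperature) - 1e-6)
  G_max <- skin_irradiation(0, 600, sc$ambient_temperature,
                            moxitherm:::scenario_geometry(sc), sc$surfaces)
  T_eq <- (G_max / 5.67e-8)^0.25 - 273.15
  expect_lt(max(vals), T_eq)
})
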