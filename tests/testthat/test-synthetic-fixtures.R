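test_that("packaged tables match the published values (spot checks)", {
  t1 <- load_fixture("table1")
  expect_equal(t1$tissue, c("Skin", "Fat", "Muscle"))
  expect_equal(t1[t1$tissue == "Muscle", c("specific_heat", "density",
                                           "conductivity")],
               data.frame(specific_heat = 3421, density = 1090,
                          conductivity = 0.49), ignore_attr = TRUE)
  expect_equal(t1$conductivity, c(0.37, 0.21, 0.49))

  t2 <- load_fixture("table2")
  expect_equal(t2$burn_temperature_C, c(600, 650, 700, 600))
  expect_equal(t2[t2$level == "standard", -1],
               data.frame(burn_temperature_C = 600, stick_size_mm = 18,
                          distance_mm = 35, ambient_C = 25),
               ignore_attr = TRUE)

  t3 <- load_fixture("table3")
  expect_equal(nrow(t3), 31)
  expect_equal(t3$time_min, seq(0, 15, by = 0.5))
  expect_equal(t3$test_C[t3$time_min == 1], 41.4)
  expect_equal(t3$test_pm_C[t3$time_min == 1], 2.4)
  expect_equal(t3$simulated_C[t3$time_min == 15], 44.18)

  t6 <- load_fixture("table6")
  t7 <- load_fixture("table7")
  expect_equal(t7$temperature_C[8], 44.727)
  expect_equal(t6$temperature_C[1:3], t7$temperature_C[1:3])
  expect_false(all(t6$temperature_C == t7$temperature_C))

  expect_error(load_fixture("table4"), "unknown fixture")
})

test_that("printed deviations follow the simulated-denominator convention on
          the rows flagged consistent", {
  t3 <- load_fixture("table3")
  dev <- 100 * (t3$simulated_C - t3$test_C) / t3$simulated_C
  ok <- t3$formula_consistent
  expect_gte(sum(ok), 20)
  expect_equal(round_half_up(dev[ok], 2), t3$deviation_pct[ok],
               tolerance = 5.1e-3)
  # and the printed column never exceeds the 5% claim
  expect_lt(max(abs(t3$deviation_pct)), 5)
})

test_that("synthetic DOE responses realize the additive model and are
          reproducible", {
  d <- build_L9()
  # no noise, no effects: nine copies of the grand mean
  s0 <- synthetic_doe_spec(grand_mean = 40)
  expect_equal(generate_doe_responses(s0, d), rep(40, 9))
  # planted B effects appear as the range of B level means
  s1 <- synthetic_doe_spec(grand_mean = 40,
                           effects = list(A = c(0, 0, 0), B = c(-2, 0, 2),
                                          C = c(0, 0, 0), D = c(0, 0, 0)))
  ra <- range_analysis(d, generate_doe_responses(s1, d))
  expect_equal(ra$table$R[ra$table$factor == "B"], 4)
  expect_equal(ra$optimal_levels[["B"]], 3)
  # determinism: same seed, same vector; different seed, different vector
  s2 <- synthetic_doe_spec(grand_mean = 40, noise_sd = 0.5, seed = 123)
  expect_identical(generate_doe_responses(s2, d),
                   generate_doe_responses(s2, d))
  s3 <- synthetic_doe_spec(grand_mean = 40, noise_sd = 0.5, seed = 124)
  expect_false(identical(generate_doe_responses(s2, d),
                         generate_doe_responses(s3, d)))
  # invariants enforced
  expect_error(synthetic_doe_spec(effects = list(A = c(1, 0, 0),
                                                 B = c(0, 0, 0),
                                                 C = c(0, 0, 0),
                                                 D = c(0, 0, 0))),
               "sum to 0")
  expect_error(synthetic_doe_spec(noise_sd = -1), "noise_sd")
})

test_that("analytic problems evaluate their closed forms", {
  # uniform equilibrium reduces to T_b when metabolism is off
  u <- analytic_problem("uniform_equilibrium", q_m = 0)
  expect_equal(u$evaluate(), 37)
  u2 <- analytic_problem("uniform_equilibrium", q_m = 420, omega_b = 0.7)
  expect_equal(u2$evaluate(), 37 + 420 / (0.7 * 3617))
  # semi-infinite flux: zero rise at t = 0, sqrt growth at the surface
  s <- analytic_problem("semi_infinite_flux", q0 = 500)
  expect_equal(s$evaluate(0, 0), 0)
  expect_equal(s$evaluate(0, 4) / s$evaluate(0, 1), 2)
  alpha <- 0.37 / (1109 * 3391)
  expect_equal(s$evaluate(0, 10), 2 * 500 / 0.37 * sqrt(alpha * 10 / pi))
  # two slabs with equal conductivity collapse to one linear profile
  tw <- analytic_problem("two_slab_steady", k1 = 0.3, k2 = 0.3)
  z <- seq(0, 0.025, by = 1e-3)
  prof <- tw$evaluate(z)
  expect_equal(diff(prof) / diff(z), rep(200 / 0.3, length(z) - 1))
  # perfusion relaxation: starts at T0, ends at the equilibrium
  p <- analytic_problem("perfusion_relaxation", T0 = 30, q_m = 0)
  expect_equal(p$evaluate(t = 0), 30)
  expect_equal(p$evaluate(t = 1e7), 37)
  lam <- 0.7 * 3617 / (1090 * 3421)
  expect_equal(p$evaluate(t = 1 / lam), 37 - 7 * exp(-1))
  expect_error(analytic_problem("semi_infinite_flux", bogus = 1), "bogus")
})
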