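test_that("config validation rejects inconsistent kinetics and grids", {
  expect_error(synthetic_config(phase_taus = c(1e4, 300, 2e5)),
               "strictly increasing")
  expect_error(synthetic_config(phase_weights = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(synthetic_config(noise_sd_rel = -0.1), "non-negative")
  expect_error(synthetic_config(grid = list(t_min = 10, t_max = 2e6,
                                            points = 8)), "points >= 16")
})

test_that("noise-free transients follow the multiphase rise model", {
  cfg <- noise_free_config()
  blank <- simulate_transient(0, cfg)
  expect_true(all(blank$fluorescence == 0))

  tr <- simulate_transient(2, cfg)
  f <- tr$fluorescence
  expect_true(all(diff(f) >= 0)) # monotone rise
  # F(t_min) near Fo, F(t_max) near Fo + Fv (within the slowest-phase tail)
  fo <- 2 * cfg$f_o_per_chla
  fmax <- fo + 2 * cfg$fv_per_chla
  expect_lt(abs(f[1] - fo) / fo, 0.05)
  expect_lt(abs(f[length(f)] - fmax) / fmax,
            exp(-cfg$grid$t_max / cfg$phase_taus[3]) + 1e-4)
})

test_that("noise-free integral area is exactly affine in chlorophyll", {
  cfg <- noise_free_config()
  a1 <- integral_area(simulate_transient(1.3, cfg))
  a2 <- integral_area(simulate_transient(2.6, cfg))
  expect_equal(a2, 2 * a1, tolerance = 1e-10)
  # closed-form expected area is the oracle for the generator's slope
  expect_equal(a1, expected_integral_area(1.3, cfg), tolerance = 1e-12)
  expect_equal(expected_integral_area(c(1, 2, 3), cfg),
               expected_integral_area(1, cfg) * c(1, 2, 3))
})

test_that("seeded simulations are bit-reproducible and seeds differ in noise",
{
  cfg <- synthetic_config(seed = 99)
  t1 <- simulate_transient(3, cfg)
  t2 <- simulate_transient(3, cfg)
  expect_identical(t1$fluorescence, t2$fluorescence)
  t3 <- simulate_transient(3, cfg, seed = 100)
  expect_false(identical(t1$fluorescence, t3$fluorescence))
  expect_identical(t1$times, t3$times)

  d1 <- generate_calibration_dataset(1:5, cfg, seed = 7)
  d2 <- generate_calibration_dataset(1:5, cfg, seed = 7)
  expect_identical(d1, d2)
})

test_that("community simulation reduces to and superposes single strains", {
  cfg <- noise_free_config()
  fo_frac <- cfg$f_o_per_chla / (cfg$f_o_per_chla + cfg$fv_per_chla)
  p <- strain_profile("a", f_per_cell = 16, chla_per_cell = 0.002)

  # single strain == simulate_transient with the equivalent coefficients
  d <- 500
  com <- simulate_community(c(a = d), list(p), cfg)
  eq_cfg <- noise_free_config(
    f_o_per_chla = fo_frac * p$f_per_cell / p$chla_per_cell,
    fv_per_chla = (1 - fo_frac) * p$f_per_cell / p$chla_per_cell)
  single <- simulate_transient(d * p$chla_per_cell, eq_cfg)
  expect_equal(com$transient$fluorescence, single$fluorescence,
               tolerance = 1e-12)
  expect_equal(com$total_chl_a, d * p$chla_per_cell)

  # two identical strains at d each == one strain at 2d
  p2 <- strain_profile("b", f_per_cell = 16, chla_per_cell = 0.002)
  two <- simulate_community(c(a = d, b = d), list(p, p2), cfg)
  one <- simulate_community(c(a = 2 * d), list(p), cfg)
  expect_equal(two$transient$fluorescence, one$transient$fluorescence,
               tolerance = 1e-12)

  expect_error(simulate_community(c(zz = 1), list(p), cfg), "match")
})

test_that("mixed 5-strain gradients give near-perfect area vs cell fits", {
  profiles <- list(
    strain_profile("s1", 3, 0.0005),
    strain_profile("s2", 8, 0.001),
    strain_profile("s3", 12, 0.002),
    strain_profile("s4", 20, 0.004,
                   kinetics = list(phase_taus = c(200, 8e3, 1.5e5))),
    strain_profile("s5", 30, 0.008)
  )
  cfg <- synthetic_config(noise_sd_rel = 0.01, seed = 2024)
  scale <- seq(0.5, 6, length.out = 12)
  res <- withr::with_seed(2024, t(sapply(scale, function(s) {
    dens <- s * c(s1 = 200, s2 = 150, s3 = 100, s4 = 80, s5 = 50)
    com <- simulate_community(dens, profiles, cfg, seed = NULL)
    c(total_cells = sum(dens), area = integral_area(com$transient))
  })))
  cal <- fit_linear(res[, "total_cells"], res[, "area"])
  expect_gt(cal$r_squared, 0.99)
})

test_that("calibration datasets support slope recovery and refuse tiny n", {
  cfg <- synthetic_config(noise_sd_rel = 0.01)
  d <- generate_calibration_dataset(seq(0.5, 8, length.out = 30), cfg,
                                    seed = 3)
  cal <- fit_linear(d$chl_a, d$integral_area)
  truth <- expected_integral_area(1, cfg)
  expect_lt(abs(cal$slope - truth) / truth, 0.02)
  expect_gt(cal$r_squared, 0.99)

  expect_error(generate_calibration_dataset(c(1, 2), cfg, seed = 1),
               "at least 3")
})

test_that("detection limit behaves sensibly in the no-noise limit and is not
           improved by extra noise", {
  grid <- c(1e-4, 5e-4, 1e-3, 5e-3)
  # no noise: the smallest positive level is detectable
  expect_equal(detection_limit(noise_free_config(), blank_replicates = 10,
                               chla_grid = grid, seed = 1), 1e-4)

  # doubling the noise never lowers the detection limit (20 seeds)
  base_cfg <- synthetic_config()
  noisy_cfg <- synthetic_config(noise_sd_rel = 0.02,
                                noise_sd_abs = 2 * base_cfg$noise_sd_abs)
  lims <- vapply(1:20, function(s) {
    c(detection_limit(base_cfg, blank_replicates = 15, chla_grid = grid,
                      seed = s),
      detection_limit(noisy_cfg, blank_replicates = 15, chla_grid = grid,
                      seed = s))
  }, numeric(2))
  expect_true(all(lims[2, ] >= lims[1, ]))
})

test_that("default generator detects 0.5 ug/L chlorophyll a", {
  lim <- detection_limit(synthetic_config(), blank_replicates = 30,
                         seed = 20)
  expect_lte(lim, 5e-4)
})
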