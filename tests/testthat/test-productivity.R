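test_that("methanol-extract chlorophyll formula evaluates correctly", {
  expect_equal(chl_a_from_absorbance(0, 0), 0)
  expect_equal(chl_a_from_absorbance(0.5, 0.2), 6.528)
  expect_equal(chl_a_from_absorbance(0.1, 0.1), 0.756)
  expect_error(chl_a_from_absorbance(-0.1, 0), "non-negative")
  # below-detection extracts clamp to zero with a warning, not an error
  expect_warning(out <- chl_a_from_absorbance(0.01, 0.5), "clamped")
  expect_equal(out, 0)
})

test_that("empirical productivity formula is linear with no hidden defaults", {
  p <- productivity_params(K = 2, r_assim = 0.25, DH = 2) # K*r*DH = 1
  expect_equal(productivity_from_chla(0, p), 0)
  expect_equal(productivity_from_chla(c(3.2, 7), p), c(3.2, 7))
  p2 <- productivity_params(K = 1.5, r_assim = 2, DH = 10)
  expect_equal(productivity_from_chla(4, p2), 1.5 * 2 * 4 * 10)

  expect_error(productivity_params(), "no defaults")
  expect_error(productivity_from_chla(1), "params")
  expect_error(productivity_params(K = -1, r_assim = 1, DH = 1), "> 0")
  expect_equal(productivity_params(K = 1, r_assim = 1, DH = 1)$PQ, 1.25)

  expect_equal(chla_mgL_to_mgm3(6.46), 6460)
})

test_that("oxygen-to-carbon conversion applies 0.375/PQ", {
  expect_equal(oxygen_to_carbon(1, pq = 1.25), 0.3)
  expect_equal(oxygen_to_carbon(0, pq = 1.25), 0)
  expect_equal(oxygen_to_carbon(10, pq = 1.0), 3.75)
  # linear and strictly decreasing in PQ
  expect_equal(oxygen_to_carbon(c(2, 4), pq = 1.25),
               2 * oxygen_to_carbon(c(1, 2), pq = 1.25))
  expect_gt(oxygen_to_carbon(1, pq = 1.0), oxygen_to_carbon(1, pq = 1.5))
  expect_error(oxygen_to_carbon(1, pq = 0), "positive")
  expect_warning(oxygen_to_carbon(-5, pq = 1.25), "heterotrophy")
})

test_that("compose_linear matches the pointwise evaluation oracle", {
  qa <- quantity("integral area", "1e10 a.u.*us", 1e10)
  qb <- quantity("P", "1e2 mg C m-3 d-1")
  qc <- quantity("P oxygen", "1e2 mg C m-3 d-1")
  set.seed(13)
  inner <- linear_calibration(runif(1, 0.1, 2), runif(1, -3, 3),
                              x_quantity = qa, y_quantity = qb)
  outer <- linear_calibration(runif(1, 0.5, 15), runif(1, -10, 10),
                              x_quantity = qb, y_quantity = qc)
  comp <- compose_linear(inner, outer)
  xs <- runif(100, -50, 50)
  expect_equal(predict(comp, xs), predict(outer, predict(inner, xs)),
               tolerance = 1e-10)
  expect_identical(comp$x_quantity, inner$x_quantity)
  expect_identical(comp$y_quantity, outer$y_quantity)
  expect_true(is.na(comp$r_squared))

  # identity composition leaves the line unchanged
  ident <- linear_calibration(1, 0, x_quantity = qb, y_quantity = qb)
  comp_id <- compose_linear(inner, ident)
  expect_equal(comp_id$slope, inner$slope)
  expect_equal(comp_id$intercept, inner$intercept)

  # associativity of chained affine maps
  third <- linear_calibration(0.7, 2, x_quantity = qc,
                              y_quantity = quantity("z", "1e2 mg C m-3 d-1"))
  left <- compose_linear(compose_linear(inner, outer), third)
  right <- compose_linear(inner, compose_linear(outer, third))
  expect_equal(left$slope, right$slope, tolerance = 1e-12)
  expect_equal(left$intercept, right$intercept, tolerance = 1e-12)

  # unit mismatch is refused
  bad <- linear_calibration(1, 0, x_quantity = quantity("other", "K"),
                            y_quantity = qc)
  expect_error(compose_linear(inner, bad), "cannot compose")
})

test_that("cross-calibration recovers a constructed correction exactly", {
  qa <- quantity("integral area", "1e10 a.u.*us", 1e10)
  qb <- quantity("P", "1e2 mg C m-3 d-1")
  base <- linear_calibration(0.5, -1, x_quantity = qa, y_quantity = qb)

  ojip <- c(10, 14, 22, 30, 41)
  # oxygen measurements generated with a known affine correction, noise-free
  a <- 1.8; b <- -2.5
  modified <- cross_calibrate(ojip, a * ojip + b, base)
  corr <- attr(modified, "correction")
  expect_equal(corr$slope, a, tolerance = 1e-10)
  expect_equal(corr$intercept, b, tolerance = 1e-10)
  expect_equal(modified$slope, a * base$slope, tolerance = 1e-10)
  expect_equal(modified$intercept, a * base$intercept + b, tolerance = 1e-10)

  # identity correction: modified equals base
  same <- cross_calibrate(ojip, ojip, base)
  expect_equal(same$slope, base$slope, tolerance = 1e-10)
  expect_equal(same$intercept, base$intercept, tolerance = 1e-10)
})

test_that("proportionality cross-check detects scalar-multiple calibrations", {
  chl <- linear_calibration(0.594, -0.9021)
  prod <- linear_calibration(0.594 * 0.2396, -0.9021 * 0.2396)
  res <- check_proportional(chl, prod)
  expect_true(res$proportional)
  expect_equal(res$ratio, 0.2396, tolerance = 1e-12)

  off <- linear_calibration(0.594 * 0.24, -0.9021 * 0.3)
  expect_false(check_proportional(chl, off)$proportional)
})
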