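test_that("closed valve coapts fully at severity zero for every preset", {
  for (p in c("healthy", "P3like", "P2like")) {
    fam <- make_mv_family(p, severity = 0)
    expect_lt(mvo_area(extract_orifice(fam$closed_config)), 1e-6)
  }
})

test_that("effective orifice area grows continuously with severity", {
  for (p in c("healthy", "P3like", "P2like")) {
    sev <- seq(0, 1, by = 0.2)
    eoa <- sapply(sev, function(s)
      mvo_area(extract_orifice(make_mv_family(p, s)$closed_config)))
    expect_true(all(diff(eoa) > 0))
  }
})

test_that("annulus is identical across severities", {
  f0 <- make_mv_family("P2like", 0)
  f1 <- make_mv_family("P2like", 1)
  expect_equal(f0$annulus_curve, f1$annulus_curve, tolerance = 1e-12)
  ## annulus row (s = 0) of the closed leaflets is untouched by the defect
  expect_equal(f0$closed_config$posterior$x[, 1],
               f1$closed_config$posterior$x[, 1], tolerance = 1e-12)
})

test_that("severity_for_eoa reaches the printed normalized orifice areas", {
  s <- severity_for_eoa("P3like", 0.11 * 4.83)
  fam <- make_mv_family("P3like", s)
  expect_equal(mvo_area(extract_orifice(fam$closed_config)) / fam$MVA,
               0.11, tolerance = 1e-3)
})

test_that("valve interpolation reproduces the stored endpoints exactly", {
  fam <- make_mv_family("P3like", 0.6)
  iv0 <- interpolate_valve(fam, 0, 0)
  expect_identical(iv0$anterior$x, fam$closed_config$anterior$x)
  expect_identical(iv0$posterior$z, fam$closed_config$posterior$z)
  iv1 <- interpolate_valve(fam, pi / 2, pi / 2)
  expect_identical(iv1$anterior$y, fam$open_config$anterior$y)
  expect_identical(iv1$posterior$x, fam$open_config$posterior$x)
})

test_that("leaflets move independently: one angle leaves the other leaflet", {
  fam <- make_mv_family("healthy", 0)
  iv <- interpolate_valve(fam, pi / 4, 0)
  expect_identical(iv$posterior$x, fam$closed_config$posterior$x)
  expect_false(isTRUE(all.equal(iv$anterior$x,
                                fam$closed_config$anterior$x)))
})

test_that("interpolation is continuous in the opening angles", {
  fam <- make_mv_family("P2like", 0.5)
  base <- interpolate_valve(fam, 0.7, 0.9)
  pert <- interpolate_valve(fam, 0.7 + 1e-3, 0.9)
  leaflen <- max(dist(cbind(as.vector(base$anterior$x),
                            as.vector(base$anterior$y),
                            as.vector(base$anterior$z))[c(1, 100), ]))
  jump <- max(abs(pert$anterior$x - base$anterior$x),
              abs(pert$anterior$z - base$anterior$z))
  expect_lt(jump, 1e-2 * max(leaflen, 1))
})

test_that("angle derivative converges at second order in the step", {
  fam <- make_mv_family("healthy", 0)
  d_exact <- valve_config_derivative(fam, pi / 4, pi / 4, 1, h = 1e-6)
  err <- sapply(c(2e-2, 1e-2, 5e-3), function(h) {
    d <- valve_config_derivative(fam, pi / 4, pi / 4, 1, h = h)
    max(abs(d$dx - d_exact$dx), abs(d$dz - d_exact$dz))
  })
  expect_gt(err[1] / err[2], 3.4)
  expect_gt(err[2] / err[3], 3.4)
})

test_that("derivative magnitude is larger at the trailing edge than the annulus", {
  fam <- make_mv_family("healthy", 0)
  d <- valve_config_derivative(fam, pi / 4, pi / 4, 2)
  mag <- sqrt(d$dx^2 + d$dy^2 + d$dz^2)
  expect_lt(max(mag[, 1]), 1e-10)          # hinged at the annulus
  expect_gt(mean(mag[, ncol(mag)]), 0.1)   # free trailing edge sweeps
})

test_that("out-of-range opening angles are rejected", {
  fam <- make_mv_family("healthy", 0)
  expect_error(interpolate_valve(fam, -0.1, 0), "angles")
  expect_error(interpolate_valve(fam, 0, 2), "angles")
})
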