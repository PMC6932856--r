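test_that("enclosed volume matches closed forms on analytic surfaces", {
  expect_equal(lv_volume(sphere_surface(1, 64)), 4 * pi / 3,
               tolerance = 2e-3)
  expect_equal(lv_volume(hemisphere_surface(2, 64), cap_plane = list(z = 0)),
               16 * pi / 3, tolerance = 2e-3)
  ## ellipsoid (1,2,3): analytic volume 8 pi (cross-checked against a
  ## 1e7-sample Monte-Carlo hit-or-miss oracle: 25.130 +- 0.008 vs 25.133)
  expect_equal(lv_volume(ellipsoid_surface(1, 2, 3, 96)), 8 * pi,
               tolerance = 2e-3)
})

test_that("volume quadrature error decreases at least second order", {
  err <- sapply(c(16, 32, 64), function(n)
    abs(lv_volume(sphere_surface(1, n)) - 4 * pi / 3))
  expect_gt(err[1] / err[2], 3.5)
  expect_gt(err[2] / err[3], 3.5)
})

test_that("open surfaces without a matching cap plane are rejected", {
  expect_error(lv_volume(hemisphere_surface(2, 32)), "open surface")
  expect_error(lv_volume(hemisphere_surface(2, 32), cap_plane = list(z = 3)),
               "open surface")
  th_open <- structured_surface(matrix(runif(25), 5), matrix(runif(25), 5),
                                matrix(runif(25), 5))
  expect_error(lv_volume(th_open), "theta-closed")
})

test_that("volume waveform is periodic with the stated extrema and phases", {
  wf <- volume_waveform(EDV = 113.47, ESV = 46.52)
  expect_equal(wf$volume(0), wf$volume(wf$period), tolerance = 1e-12)
  expect_equal(max(wf$V), wf$EDV, tolerance = 1e-6)
  expect_equal(min(wf$V), wf$ESV, tolerance = 1e-6)
  expect_equal(wf$SV, wf$EDV - wf$ESV)
  expect_equal(wf$EF, wf$SV / wf$EDV)
  ## systole is the contiguous interval where dV/dt < 0
  t <- seq(0, 1, by = 1e-3)
  neg <- which(wf$dvdt(t) < -1e-9)
  expect_true(all(diff(neg) == 1))
  expect_true(all(phase_of(wf, t[neg]) == "systole"))
})

test_that("synthetic ventricle tracks the prescribed volume on both presets", {
  for (name in c("healthy", "dilated")) {
    p <- lv_preset(name)
    lv <- make_lv_surface(p$shape_params, p$waveform, 64, 32)
    ts <- seq(0, 1, by = 0.1)
    err <- sapply(ts, function(t)
      abs(lv_volume(lv_surface_at(lv, t), cap_plane = list(z = 0)) -
            p$waveform$volume(t)))
    expect_lt(max(err) / p$waveform$SV, 0.005)
  }
})

test_that("end-diastolic and end-systolic cavity volumes match the presets", {
  ph <- lv_preset("healthy")
  lvh <- make_lv_surface(ph$shape_params, ph$waveform, 64, 32)
  expect_equal(lv_volume(lv_surface_at(lvh, 0), cap_plane = list(z = 0)),
               113.47, tolerance = 0.005)
  pd <- lv_preset("dilated")
  lvd <- make_lv_surface(pd$shape_params, pd$waveform, 64, 32)
  expect_equal(lv_volume(lv_surface_at(lvd, pd$waveform$t_end_systole),
                         cap_plane = list(z = 0)),
               142.50, tolerance = 0.005)
})

test_that("node velocities equal the time derivative of positions", {
  p <- lv_preset("healthy")
  lv <- make_lv_surface(p$shape_params, p$waveform, 24, 12)
  for (t0 in c(0.1, 0.3, 0.55, 0.85)) {
    dt <- 1e-5
    sp <- lv_surface_at(lv, t0 + dt); sm <- lv_surface_at(lv, t0 - dt)
    s0 <- lv_surface_at(lv, t0)
    expect_lt(max(abs((sp$x - sm$x) / (2 * dt) - s0$vx),
                  abs((sp$y - sm$y) / (2 * dt) - s0$vy),
                  abs((sp$z - sm$z) / (2 * dt) - s0$vz)), 1e-4)
  }
})

test_that("a constant waveform yields a static ventricle", {
  wf <- volume_waveform(EDV = 100, ESV = 99.999)
  wf$volume <- function(t) rep(100, length(t))
  wf$dvdt <- function(t) rep(0, length(t))
  lv <- make_lv_surface(list(c0 = 4.5, cos_base = 0.42), wf, 16, 8)
  s <- lv_surface_at(lv, 0.3)
  expect_lt(max(abs(s$vx), abs(s$vy), abs(s$vz)), 1e-10)
})

test_that("infeasible volume ranges raise a geometry error", {
  wf <- volume_waveform(EDV = 100, ESV = 5)
  expect_error(make_lv_surface(list(c0 = 4.5, cos_base = 0.42), wf),
               "infeasible")
})
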