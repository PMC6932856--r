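test_that("uniform concentration is preserved by any solenoidal flow", {
  g <- build_grid(list(x = c(0, 2 * pi), y = c(0, 2 * pi),
                       z = c(0, 2 * pi)), 16, 16, 16)
  flow <- taylor_green_flow(g)
  C <- array(0.37, c(16, 16, 16))
  C2 <- advance_scalar(C, flow, g, 5e-3, kappa = 0.02, zper = TRUE)
  expect_equal(max(abs(C2 - 0.37)), 0, tolerance = 1e-13)
})

test_that("pure diffusion spreads a Gaussian blob at the analytic rate", {
  n <- 48; L <- 2 * pi
  g <- build_grid(list(x = c(0, L), y = c(0, L), z = c(0, L)), n, n, n)
  cc <- cell_centers(g)
  s0 <- 0.25; kappa <- 0.05
  r2 <- outer(outer((cc$x - L / 2)^2, (cc$y - L / 2)^2, `+`),
              (cc$z - L / 2)^2, `+`)
  C <- 0.5 * exp(-r2 / (2 * s0^2))
  flow <- ventriflow:::empty_flow(g)
  t <- 0; tend <- 0.2; dt <- 2e-3
  while (t < tend - 1e-12) {
    C <- advance_scalar(C, flow, g, dt, kappa, zper = TRUE)
    t <- t + dt
  }
  ## measured variance along x
  wx <- apply(C, 1, sum)
  mu <- sum(wx * cc$x) / sum(wx)
  varx <- sum(wx * (cc$x - mu)^2) / sum(wx)
  expect_equal(varx, s0^2 + 2 * kappa * tend, tolerance = 0.01)
})

test_that("solid-body rotation returns a blob and conserves mass", {
  n <- 48; L <- 2
  g <- build_grid(list(x = c(-L, L), y = c(-L, L), z = c(0, 1)),
                  n, n, 8)
  cc <- cell_centers(g)
  omega <- 2 * pi              # one revolution per unit time
  ## solid-body rotation about the box center (periodic images negligible
  ## because the blob stays near the center)
  flow <- ventriflow:::empty_flow(g)
  for (j in 1:n) flow$u[, j, ] <- -omega * cc$y[j]
  for (i in 1:n) flow$v[i, , ] <- omega * cc$x[i]
  C <- array(0, c(n, n, 8))
  r2 <- outer((cc$x - 0.8)^2, cc$y^2, `+`)
  for (k in 1:8) C[, , k] <- exp(-r2 / (2 * 0.15^2))
  mass0 <- sum(C)
  t <- 0; dt <- 2.5e-3
  while (t < 1 - 1e-12) {
    C <- advance_scalar(C, flow, g, dt, kappa = 0, zper = TRUE)
    t <- t + dt
  }
  ## center of mass back at the start within one cell
  w <- apply(C, c(1, 2), sum)
  mux <- sum(w * outer(cc$x, rep(1, n))) / sum(w)
  muy <- sum(w * outer(rep(1, n), cc$y)) / sum(w)
  expect_lt(sqrt((mux - 0.8)^2 + muy^2), max(g$hx, g$hy))
  expect_equal(sum(C) / mass0, 1, tolerance = 1e-3)
  expect_gte(min(C), 0)
  expect_lte(max(C), 1)
})

test_that("residual volume is the C-weighted cavity fraction", {
  p <- lv_preset("healthy")
  lv <- make_lv_surface(p$shape_params, p$waveform, 32, 16)
  fam <- make_mv_family("healthy", 0)
  asm <- compose_domain(lv, fam)
  g <- build_grid(asm$box, 20, 20, 30)
  tes <- p$waveform$t_end_systole
  vs <- valve_surfaces_at(asm$mv, valve_state(0, 0))
  tag <- tag_immersed_cells(g, asm, vs, tes, av_open = FALSE)
  flow <- ventriflow:::empty_flow(g); flow$t <- tes
  C <- init_marker(flow, tag, g)
  ## marker fills the cavity fluid cells: its integral approximates ESV
  ## minus the volume occupied by the leaflet and wall cut cells (an O(h)
  ## share at this coarse grid)
  vol <- sum(C) * g$hx * g$hy * g$hz
  expect_equal(vol, p$waveform$ESV, tolerance = 0.16)
  ## no marker above the valve plane (tubes/atrium)
  cc <- cell_centers(g)
  expect_equal(max(C[, , cc$z > 0]), 0)
  ## boundary cells carry no marker
  expect_equal(max(C[tag$mask != 0L]), 0)
  ## residual_volume is linear in C
  expect_equal(residual_volume(C, tag$mask, g, p$waveform$ESV),
               vol / p$waveform$ESV)
  expect_equal(residual_volume(0.5 * C, tag$mask, g, p$waveform$ESV),
               0.5 * vol / p$waveform$ESV)
  expect_equal(residual_volume(C * 0, tag$mask, g, p$waveform$ESV), 0)
})
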