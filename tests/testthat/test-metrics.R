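## simple two-edge fixture: parallel straight trailing edges
parallel_orifice <- function(gap = 0.3, len = 2, n = 21) {
  y <- seq(0, len, length.out = n)
  ## leaflet surfaces whose last s-column is the edge; interior columns
  ## displaced so facets are non-degenerate
  ant <- structured_surface(outer(rep(gap / 2, n), c(1.5, 1.25, 1, 1, 1)),
                            outer(y, rep(1, 5)),
                            matrix(rep(c(0.4, 0.3, 0.2, 0.1, 0), each = n),
                                   n, 5))
  post <- structured_surface(outer(rep(-gap / 2, n), c(1.5, 1.25, 1, 1, 1)),
                             outer(y, rep(1, 5)),
                             matrix(rep(c(0.4, 0.3, 0.2, 0.1, 0), each = n),
                                    n, 5))
  list(anterior = ant, posterior = post)
}

test_that("orifice extraction measures parallel edges exactly", {
  vs <- parallel_orifice(gap = 0.3, len = 2)
  o <- extract_orifice(vs)
  expect_equal(max(abs(o$gap - 0.3)), 0, tolerance = 1e-12)
  expect_equal(max(o$arclength), 2, tolerance = 1e-12)
  expect_equal(mvo_area(o), 0.6, tolerance = 1e-12)
})

test_that("coapting edges give zero orifice area", {
  vs <- parallel_orifice(gap = 0, len = 2)
  o <- extract_orifice(vs)
  expect_equal(mvo_area(o), 0, tolerance = 1e-12)
})

test_that("prolapse presets localize the gap at the defect sector", {
  fam <- make_mv_family("P2like", 0.8)
  o <- extract_orifice(fam$closed_config)
  n <- length(o$gap)
  mid <- o$gap[(n %/% 3):(2 * n %/% 3)]     # central (P2) sector
  ends <- c(o$gap[1:(n %/% 6)], o$gap[(n - n %/% 6):n])
  expect_gt(max(mid), 10 * max(max(ends), 1e-6))
})

test_that("orifice area quadrature converges on a smooth gap profile", {
  gapf <- function(y) 0.2 + 0.1 * sin(pi * y / 2)
  area_n <- function(n) {
    y <- seq(0, 2, length.out = n)
    s <- seq(0, 1, length.out = 5)
    shift <- c(0.4, 0.3, 0.2, 0.1, 0)
    ant <- structured_surface(outer(gapf(y) / 2, rep(1, 5)) + 1e-9,
                              outer(y, rep(1, 5)),
                              matrix(rep(shift, each = n), n, 5))
    post <- structured_surface(outer(-gapf(y) / 2, rep(1, 5)),
                               outer(y, rep(1, 5)),
                               matrix(rep(shift, each = n), n, 5))
    mvo_area(extract_orifice(list(anterior = ant, posterior = post)))
  }
  exact <- integrate(gapf, 0, 2)$value
  e1 <- abs(area_n(11) - exact)
  e2 <- abs(area_n(21) - exact)
  e3 <- abs(area_n(41) - exact)
  expect_gt(e1 / e2, 3); expect_gt(e2 / e3, 3)
})

test_that("orifice flow integrates uniform and manufactured velocity fields", {
  vs <- parallel_orifice(gap = 0.4, len = 2)
  o <- extract_orifice(vs)
  ## uniform flow along the station normal (+z here)
  q <- orifice_flow(field_sampler(function(p) c(0, 0, 2.5)), o)
  expect_equal(q, 2.5 * 0.4 * 2, tolerance = 1e-10)
  ## fluid moving with the edges yields zero relative flux
  vs2 <- parallel_orifice(gap = 0.4, len = 2)
  for (leaf in c("anterior", "posterior")) {
    vs2[[leaf]]$vx[] <- 0; vs2[[leaf]]$vy[] <- 0; vs2[[leaf]]$vz[] <- 1.7
  }
  o2 <- extract_orifice(vs2)
  q2 <- orifice_flow(field_sampler(function(p) c(0, 0, 1.7)), o2)
  expect_equal(q2, 0, tolerance = 1e-10)
  ## smooth field against a dense-sampling quadrature oracle
  f <- function(p) c(0, 0, 1 + 0.5 * sin(p[2]) + 0.3 * p[1])
  q3 <- orifice_flow(field_sampler(f), o, n_gauss = 5)
  oracle <- orifice_flow(field_sampler(f), {
    vsd <- parallel_orifice(gap = 0.4, len = 2, n = 401)
    extract_orifice(vsd)
  }, n_gauss = 24)
  expect_equal(q3, oracle, tolerance = 0.005 * abs(oracle))
})

test_that("old-blood flux is the concentration-weighted orifice flux", {
  vs <- parallel_orifice(gap = 0.3, len = 2)
  o <- extract_orifice(vs)
  sampler <- field_sampler(function(p) c(0, 0, 1 + 0.2 * p[2]))
  q <- orifice_flow(sampler, o)
  for (c0 in c(0, 0.5, 1)) {
    qc <- orifice_flow(sampler, o, weight = function(p) rep(c0, nrow(p)))
    expect_equal(qc, c0 * q, tolerance = 1e-12)
  }
})

test_that("annulus flow measures uniform and relative fluxes", {
  sampler <- field_sampler(function(p) c(0, 0, 3))
  q <- annulus_flow(sampler, c(0, 0, 0), radius = 1.2)
  expect_equal(q, 3 * pi * 1.2^2, tolerance = 1e-6)
  q0 <- annulus_flow(sampler, c(0, 0, 0), radius = 1.2,
                     annulus_velocity = c(0, 0, 3))
  expect_equal(q0, 0, tolerance = 1e-12)
})

test_that("phase integration splits a trace by the waveform sign", {
  wf <- volume_waveform(100, 50)
  t <- seq(0, 1, by = 1e-3)
  series <- data.frame(t = t, Q = rep(10, length(t)))
  vs <- integrate_phase(series, "systole", "Q", wf)
  vd <- integrate_phase(series, "diastole", "Q", wf)
  expect_equal(vs + vd, 10, tolerance = 1e-9)
  expect_equal(vs, 10 * wf$t_end_systole, tolerance = 0.02)
  ## antisymmetric flux about mid-systole cancels
  tm <- wf$t_end_systole / 2
  series$Q <- ifelse(t < wf$t_end_systole + 1e-9, t - tm, 0)
  expect_equal(integrate_phase(series, "systole", "Q", wf), 0,
               tolerance = 1e-6)
  expect_error(integrate_phase(series[1:1, ], "systole", "Q", wf),
               "phase")
})

test_that("report normalizations reproduce the published worked examples", {
  ## healthy-ventricle P3 prolapse row
  r <- metric_report(MVA = 4.83, EOA = 0.52, SV = 66.95,
                     VregMVa = 8.87, Vreg = 6.29)
  expect_equal(r$Vregfalse, 2.58)
  expect_equal(r$EOA_MVA_pct, 11, tolerance = 0.05)
  expect_equal(r$Vreg_SV_pct, 9.40, tolerance = 0.005)
  ## P2 row
  r2 <- metric_report(MVA = 4.26, EOA = 0.87, SV = 66.95,
                      VregMVa = 13.42, Vreg = 12.76, Vregold = 6.42)
  expect_equal(r2$Vreg_SV_pct, 19.07, tolerance = 0.005)
  expect_equal(r2$Vregold_Vreg_pct, 50.31, tolerance = 0.005)
})

test_that("the false-regurgitation identity holds to machine precision", {
  set.seed(9)
  for (i in 1:20) {
    v <- sort(runif(2, 0, 20))
    r <- metric_report(MVA = 5, EOA = 0.5, SV = 60,
                       VregMVa = v[2], Vreg = v[1])
    expect_identical(r$Vregfalse, v[2] - v[1])
  }
})
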