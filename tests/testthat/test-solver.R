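test_that("grid accessors are consistent and invertible", {
  g <- build_grid(list(x = c(0, 4), y = c(0, 4), z = c(0, 8)), 32, 32, 64)
  expect_equal(c(g$hx, g$hy, g$hz), c(0.125, 0.125, 0.125))
  ## face index <-> coordinate round trip
  for (comp in c("u", "v", "w")) {
    p <- face_coord(g, comp, 5, 7, 9)
    expect_equal(face_index(g, comp, as.vector(p)), c(5, 7, 9))
  }
  expect_error(build_grid(list(x = c(0, 1), y = c(0, 1), z = c(0, 1)),
                          0, 8, 8), "positive")
})

test_that("Poisson solver reproduces a manufactured solution to round-off", {
  g <- build_grid(list(x = c(0, 2), y = c(0, 3), z = c(0, 1)), 24, 18, 20)
  cc <- cell_centers(g)
  phi <- outer(outer(cos(2 * pi * cc$x / 2), sin(2 * pi * cc$y / 3)),
               cos(pi * cc$z / 2))
  rhs <- ventriflow:::laplacian_ref(phi, g)
  sol <- solve_poisson(rhs, g)
  expect_lt(max(abs(sol - phi)) / max(abs(phi)), 1e-12)
})

test_that("manufactured continuous solution converges at second order", {
  f <- function(n) {
    g <- build_grid(list(x = c(0, 2), y = c(0, 2), z = c(0, 1)),
                    n, n, n)
    cc <- cell_centers(g)
    exact <- outer(outer(cos(pi * cc$x), sin(pi * cc$y)),
                   cos(pi * cc$z / 2))
    lap <- -(pi^2 + pi^2 + (pi / 2)^2) * exact
    sol <- solve_poisson(lap, g)
    max(abs(sol - exact))
  }
  errs <- sapply(c(16, 32, 64), f)
  expect_gt(errs[1] / errs[2], 3.5); expect_lt(errs[1] / errs[2], 4.5)
  expect_gt(errs[2] / errs[3], 3.5); expect_lt(errs[2] / errs[3], 4.5)
})

test_that("projection annihilates the gradient part of a random field", {
  set.seed(3)
  g <- build_grid(list(x = c(0, 3), y = c(0, 3), z = c(0, 3)), 24, 24, 24)
  flow <- ventriflow:::empty_flow(g)
  flow$u[] <- rnorm(length(flow$u))
  flow$v[] <- rnorm(length(flow$v))
  flow$w[] <- rnorm(length(flow$w))
  sim <- list(grid = g, nu = 0.04, zper = FALSE, assembly = NULL)
  pr <- ventriflow:::force_and_project(flow, sim, NULL, 0.01)
  dv <- ventriflow:::divergence(pr$u, pr$v, pr$w, g$nx, g$ny, g$nz,
                                g$hx, g$hy, g$hz)
  expect_lt(max(abs(dv)), 1e-8)
  ## idempotence: projecting again changes nothing
  pr2 <- ventriflow:::force_and_project(pr, sim, NULL, 0.01)
  expect_equal(pr2$u, pr$u, tolerance = 1e-10)
})

test_that("zero velocity with static boundaries stays at rest", {
  g <- build_grid(list(x = c(-2, 2), y = c(-2, 2), z = c(0, 4)), 16, 16, 16)
  flow <- ventriflow:::empty_flow(g)
  sim <- list(grid = g, nu = 0.04, zper = FALSE, assembly = NULL,
              cfl_max = 0.5, scalar_active = FALSE, av = list(open = FALSE))
  st <- advance(flow, sim, 1e-3)
  expect_equal(max(abs(st$flow$u)), 0)
  expect_equal(max(abs(st$flow$w)), 0)
})

test_that("masked projection matches the box solve on an all-fluid mask", {
  set.seed(5)
  g <- build_grid(list(x = c(0, 2), y = c(0, 2), z = c(0, 2)), 12, 12, 12)
  rhs <- array(rnorm(12^3), c(12, 12, 12))
  mask <- array(0L, c(12, 12, 12))
  sol <- solve_poisson_masked(rhs, g, mask, rtol = 1e-12, maxit = 50)
  expect_lt(max(abs(sol$phi - solve_poisson(rhs, g))), 1e-8)
})

test_that("tagging a static sphere yields a thin boundary shell", {
  g <- build_grid(list(x = c(-2, 2), y = c(-2, 2), z = c(0, 4)), 24, 24, 24)
  n <- 24L
  mask <- integer(24^3); prio <- integer(24^3)
  bu <- numeric(24^3); bv <- numeric(24^3); bw <- numeric(24^3)
  fac <- ventriflow:::surface_facets(sphere_surface(1, 48, c(0, 0, 2)))
  keep <- fac$area > 1e-14
  vel <- matrix(rep(c(0.7, -0.2, 0.4), each = sum(keep)), ncol = 3)
  ventriflow:::mark_facets(mask, prio, bu, bv, bw,
                           fac$a[keep, ], fac$b[keep, ], fac$c[keep, ],
                           vel, 1L, n, n, n, g$x0, g$y0, g$z0,
                           g$hx, g$hy, g$hz)
  count <- sum(mask == 1L)
  ## voxelization heuristic: area / h^2 cells, within a factor accounting
  ## for the sqrt(3) diagonal spread
  area <- 4 * pi
  expect_gt(count, area / g$hx^2 * 0.8)
  expect_lt(count, area / g$hx^2 * sqrt(3) * 1.35)
  ## rigid translation velocity carried by every boundary cell
  expect_equal(unique(bu[mask == 1L]), 0.7)
  expect_equal(unique(bw[mask == 1L]), 0.4)
})

test_that("domain tagging is watertight and classifies tubes as fluid", {
  p <- lv_preset("healthy")
  lv <- make_lv_surface(p$shape_params, p$waveform, 32, 16)
  fam <- make_mv_family("healthy", 0)
  asm <- compose_domain(lv, fam)
  g <- build_grid(asm$box, 20, 20, 30)
  vs <- valve_surfaces_at(fam_t <- asm$mv, valve_state(pi / 2, pi / 2))
  tag <- tag_immersed_cells(g, asm, vs, 0.1, av_open = FALSE)
  expect_setequal(unique(as.vector(tag$mask)), c(0L, 1L, 2L))
  cc <- cell_centers(g)
  probe <- function(p) {
    i <- findInterval(p[1], g$x0 + (0:g$nx) * g$hx)
    j <- findInterval(p[2], g$y0 + (0:g$ny) * g$hy)
    k <- findInterval(p[3], g$z0 + (0:g$nz) * g$hz)
    tag$mask[i, j, k]
  }
  ## mid-cavity and tube interiors are fluid; outside the wall is exterior
  expect_equal(probe(c(0, 0, -2)), 0L)
  expect_equal(probe(c(asm$tubes$atrium$center[1], 0, 1.5)), 0L)
  expect_equal(probe(c(asm$box$x[2] - 0.2, asm$box$y[2] - 0.2, -2)), 2L)
  ## with an open mitral valve the cavity is connected to the top (vented)
  expect_length(tag$sealed_ids, 0)
  ## with the valve closed and the aortic patch shut, the cavity seals
  vsc <- valve_surfaces_at(asm$mv, valve_state(0, 0))
  tagc <- tag_immersed_cells(g, asm, vsc, 0.1, av_open = FALSE)
  expect_gt(length(tagc$sealed_ids), 0)
})

test_that("assembly audit passes for presets and rejects bad layouts", {
  p <- lv_preset("dilated")
  lv <- make_lv_surface(p$shape_params, p$waveform, 24, 12)
  fam <- make_mv_family("P2like", 0.5)
  asm <- compose_domain(lv, fam)
  expect_true(assembly_watertight(asm))
  expect_gte(asm$AMVa, fam$MVA * 0.99)   # annulus area >= valve area
  expect_error(compose_domain(lv, fam, list(radius = 3.5)), "layout")
})

test_that("restart from a checkpoint reproduces the trajectory bitwise", {
  n <- 12
  g <- build_grid(list(x = c(0, 2 * pi), y = c(0, 2 * pi),
                       z = c(0, 2 * pi)), n, n, n)
  flow <- taylor_green_flow(g)
  sim <- list(grid = g, nu = 0.04, zper = TRUE, assembly = NULL,
              cfl_max = 0.6, scalar_active = FALSE, av = list(open = FALSE))
  for (i in 1:3) flow <- advance(flow, sim, 1e-3)$flow
  tmp <- tempfile(fileext = ".rds")
  save_checkpoint(list(flow = flow, config = run_config()), tmp)
  cont1 <- flow
  for (i in 1:3) cont1 <- advance(cont1, sim, 1e-3)$flow
  cont2 <- load_checkpoint(tmp)$flow
  for (i in 1:3) cont2 <- advance(cont2, sim, 1e-3)$flow
  expect_identical(cont1$u, cont2$u)
  expect_identical(cont1$w, cont2$w)
})
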