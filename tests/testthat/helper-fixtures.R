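## analytic surface builders used across tests

sphere_surface <- function(r = 1, n = 64, center = c(0, 0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  ps <- seq(0, pi, length.out = n + 1)
  structured_surface(center[1] + r * outer(cos(th), sin(ps)),
                     center[2] + r * outer(sin(th), sin(ps)),
                     center[3] + r * matrix(rep(cos(ps), each = n + 1),
                                            n + 1),
                     closed_theta = TRUE)
}

ellipsoid_surface <- function(a, b, c, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  ps <- seq(0, pi, length.out = n + 1)
  structured_surface(a * outer(cos(th), sin(ps)),
                     b * outer(sin(th), sin(ps)),
                     c * matrix(rep(cos(ps), each = n + 1), n + 1),
                     closed_theta = TRUE)
}

hemisphere_surface <- function(r = 2, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  ps <- seq(0, pi / 2, length.out = n + 1)
  structured_surface(r * outer(cos(th), sin(ps)),
                     r * outer(sin(th), sin(ps)),
                     r * matrix(rep(cos(ps), each = n + 1), n + 1),
                     closed_theta = TRUE)
}

## Taylor-Green initial condition on a fully periodic cube grid
taylor_green_flow <- function(grid, U = 1) {
  n <- grid$nx
  flow <- ventriflow:::empty_flow(grid)
  xu <- grid$x0 + (1:n) * grid$hx
  yc <- grid$y0 + ((1:grid$ny) - 0.5) * grid$hy
  xc <- grid$x0 + ((1:n) - 0.5) * grid$hx
  yv <- grid$y0 + (1:grid$ny) * grid$hy
  flow$u <- array(U * outer(sin(xu), cos(yc)), c(grid$nx, grid$ny, grid$nz))
  flow$v <- array(-U * outer(cos(xc), sin(yv)), c(grid$nx, grid$ny, grid$nz))
  flow
}

## sampler that returns a fixed analytic velocity field
field_sampler <- function(f) function(pts) t(apply(pts, 1, f))

## tiny coupled-run configuration used by smoke-style tests
tiny_run_config <- function(...) {
  run_config(utils::modifyList(
    list(nx = 20L, ny = 20L, nz = 30L, n_cycles = 1L, cfl_max = 0.9,
         poisson_rtol = 1e-3, lv_n_theta = 32L, lv_n_s = 16L,
         mv_n_theta = 20L, mv_n_s = 6L, dt_max = 2e-3),
    list(...)))
}
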