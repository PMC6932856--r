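#' Trilinear velocity sampler bound to a flow state
#'
#' @param flow list with staggered arrays `u`, `v`, `w`.
#' @param grid a [build_grid()] grid.
#' @return function mapping an `n x 3` point matrix to an `n x 3` velocity
#'   matrix (cm/s).
#' @export
flow_sampler <- function(flow, grid) {
  force(flow); force(grid)
  function(pts)
    interp_velocity(pts, flow$u, flow$v, flow$w,
                    grid$nx, grid$ny, grid$nz,
                    grid$x0, grid$y0, grid$z0, grid$hx, grid$hy, grid$hz)
}

#' Trilinear concentration sampler bound to a flow state
#' @inheritParams flow_sampler
#' @return function mapping points to scalar values.
#' @export
scalar_sampler <- function(flow, grid) {
  force(flow); force(grid)
  function(pts)
    interp_scalar(pts, flow$C, grid$nx, grid$ny, grid$nz,
                  grid$x0, grid$y0, grid$z0, grid$hx, grid$hy, grid$hz)
}

## mean normal velocity just upstream of the aortic orifice (positive toward
## the aorta); sampled two cell layers below the valve plane so that it reads
## fluid faces even when the closed orifice patch is a forced wall
aortic_mean_outflow <- function(w, grid, assembly) {
  cc <- cell_centers(grid)
  kp <- which(cc$z > -grid$hz & cc$z < 0)
  ao <- assembly$aortic
  xg <- rep(cc$x, times = grid$ny); yg <- rep(cc$y, each = grid$nx)
  inside <- which(sqrt((xg - ao$center[1])^2 + (yg - ao$center[2])^2) <
                    ao$radius)
  mean(w[, , max(kp - 1L, 1L)][inside])
}

## one explicit Euler sub-step increments (momentum, angles, scalar)
stage_increments <- function(flow, sim, tag) {
  g <- sim$grid
  mask <- if (!is.null(tag)) tag$mask else array(0L, c(g$nx, g$ny, g$nz))
  r <- momentum_rhs(flow$u, flow$v, flow$w, g$nx, g$ny, g$nz,
                    g$hx, g$hy, g$hz, sim$nu, as.integer(isTRUE(sim$zper)),
                    sim$upwind_blend %||% 0)
  out <- list(ru = array(r$ru, dim(flow$u)),
              rv = array(r$rv, dim(flow$v)),
              rw = array(r$rw, dim(flow$w)))
  if (!is.null(sim$assembly)) {
    sampler <- flow_sampler(flow, g)
    st <- valve_state(flow$phi[1], flow$phi[2])
    off <- 1.2 * max(g$hx, g$hy, g$hz)
    rates <- solve_rates(assemble_system(sim$assembly$mv, st, sampler,
                                         normal_offset = off))
    rmax <- sim$valve_rate_max %||% 40
    rates <- pmin(pmax(rates, -rmax), rmax)
    ## sub-grid aperture regime: while the discrete inter-leaflet aperture
    ## is sealed (the ventricle is a disconnected fluid pocket) the leaflets
    ## cannot be flow-driven -- the transvalvular jet does not exist on the
    ## grid. Carry them at the rate cap: opening while filling is
    ## prescribed, closing while ejection is prescribed (the flow-driven
    ## dynamics take over as soon as the aperture is resolved).
    if (!is.null(sim$waveform)) {
      dv <- sim$waveform$dvdt(flow$t)
      sealed <- !is.null(tag) && length(tag$sealed_ids) > 0
      if (dv > 1e-9 && sealed && !isTRUE(sim$av$open)) {
        rates[] <- rmax
      } else if (dv < -1e-9 && !is.null(sim$phi_res)) {
        band <- flow$phi < sim$phi_res
        rates[band] <- -rmax
      }
    }
    out$rates <- rates
  }
  if (isTRUE(sim$scalar_active)) {
    rc <- scalar_rhs(flow$C, flow$u, flow$v, flow$w, mask,
                     g$nx, g$ny, g$nz, g$hx, g$hy, g$hz, sim$kappa,
                     as.integer(isTRUE(sim$zper)))
    out$rC <- array(rc, dim(flow$C))
  }
  out
}

## force boundary faces, project, and return the corrected state
force_and_project <- function(flow, sim, tag, dt) {
  g <- sim$grid
  if (!is.null(tag)) {
    bc <- apply_face_bc(flow$u, flow$v, flow$w, tag$mask,
                        tag$bu, tag$bv, tag$bw, g$nx, g$ny, g$nz)
    flow$u <- array(bc$u, dim(flow$u))
    flow$v <- array(bc$v, dim(flow$v))
    flow$w <- array(bc$w, dim(flow$w))
  } else if (!isTRUE(sim$zper)) {
    flow$w[, , 1] <- 0
  }
  div <- array(divergence(flow$u, flow$v, flow$w, g$nx, g$ny, g$nz,
                          g$hx, g$hy, g$hz), c(g$nx, g$ny, g$nz))
  if (!is.null(tag) && length(tag$sealed_ids)) {
    ## sealed fluid pockets (both valves closed): the prescribed wall motion
    ## is incompatible with incompressibility there; remove the mean defect
    ## so the projection stays well-posed (the defect is absorbed by the
    ## valve-opening kinematics)
    for (id in tag$sealed_ids) {
      cells <- tag$labels == id
      div[cells] <- div[cells] - mean(div[cells])
    }
  }
  if (is.null(tag)) {
    phi <- solve_poisson(div / dt, g, zper = isTRUE(sim$zper))
    cr <- project_correct(flow$u, flow$v, flow$w, phi, g$nx, g$ny, g$nz,
                          g$hx, g$hy, g$hz, dt, as.integer(isTRUE(sim$zper)))
  } else {
    ## fluid-only projection: forced faces keep their boundary velocity,
    ## so the immersed walls stay impermeable; warm start from a linear
    ## extrapolation of the two previous stage solutions
    phi0 <- if (!is.null(flow$phi_prev2)) 2 * flow$phi_prev - flow$phi_prev2
            else flow$phi_prev
    sol <- solve_poisson_masked(div / dt, g, tag$mask, phi0 = phi0,
                                rtol = sim$poisson_rtol %||% 1e-8,
                                maxit = sim$poisson_maxit %||% 300L)
    phi <- sol$phi
    flow$phi_prev2 <- flow$phi_prev
    flow$phi_prev <- phi
    flow$poisson_rel <- sol$rel
    flow$poisson_iters <- sol$iterations
    cr <- project_correct_masked(flow$u, flow$v, flow$w, phi, tag$mask,
                                 g$nx, g$ny, g$nz, g$hx, g$hy, g$hz, dt)
  }
  flow$u <- array(cr$u, dim(flow$u))
  flow$v <- array(cr$v, dim(flow$v))
  flow$w <- array(cr$w, dim(flow$w))
  flow$p <- phi / dt
  flow
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## rebuild geometry-dependent state (valve surfaces, aortic valve, tagging)
## at a stage target time
retag_at <- function(flow, sim, t_target) {
  if (is.null(sim$assembly)) return(list(tag = NULL, vs = NULL, av = sim$av))
  st <- valve_state(flow$phi[1], flow$phi[2], flow$rates[1], flow$rates[2])
  vs <- valve_surfaces_at(sim$assembly$mv, st)
  open <- update_aortic_valve(
    st, aortic_mean_outflow(flow$w, sim$grid, sim$assembly),
    sim$phi_closed_tol)$open
  ## ejection onset: a sealed contracting cavity cannot generate outflow at
  ## the still-closed orifice, so the prescribed ejection also triggers the
  ## opening (the velocity criterion then sustains it)
  if (!open && !is.null(sim$waveform)) {
    mv_closed <- st$phi1 < sim$phi_closed_tol & st$phi2 < sim$phi_closed_tol
    if (mv_closed && sim$waveform$dvdt(t_target) < -1e-9) open <- TRUE
  }
  av <- list(open = open)
  tag <- tag_immersed_cells(sim$grid, sim$assembly, vs, t_target,
                            av_open = av$open)
  list(tag = tag, vs = vs, av = av)
}

#' Advance the coupled flow / valve / scalar state by one time step
#'
#' Three SSP RK3 stages. Each stage: explicit advection-diffusion update of
#' the velocity (and scalar), co-advance of the valve opening angles from the
#' flow-driven least-squares system, clamping to `[0, pi/2]`, re-tagging of
#' the immersed geometry at the stage target time, re-imposition of boundary
#' velocities on cut cells, and pressure projection.
#'
#' @param flow flow state: staggered `u`, `v`, `w`, pressure `p`, scalar
#'   `C`, time `t`, angles `phi`, angle rates `rates`.
#' @param sim simulation context: `grid`, `assembly` (or `NULL` for a
#'   body-free box), `nu`, `kappa`, `zper`, `scalar_active`,
#'   `phi_closed_tol`.
#' @param dt time step (s).
#' @param tag current cell classification (from [tag_immersed_cells()]), or
#'   `NULL`.
#' @return list with the advanced `flow`, the final-stage `tag` and `av`
#'   state.
#' @export
advance <- function(flow, sim, dt, tag = NULL) {
  g <- sim$grid
  rate <- max_cfl_rate(flow$u, flow$v, flow$w, g$nx, g$ny, g$nz,
                       g$hx, g$hy, g$hz)
  if (rate * dt > sim$cfl_max + 1e-12)
    stop("CFL violation: reduce the time step")
  has_scalar <- isTRUE(sim$scalar_active)
  combine <- function(a, f0, fs, inc, w0, ws)
    w0 * f0[[a]] + ws * (fs[[a]] + dt * inc)
  clipC <- function(C) pmin(pmax(C, 0), 1)
  f0 <- flow
  av <- sim$av
  ## stage targets: t+dt, t+dt/2, t+dt (SSP RK3)
  stage <- function(fs, w0, ws, t_target) {
    inc <- stage_increments(fs, sim, tag)
    fn <- fs
    fn$u <- combine("u", f0, fs, inc$ru, w0, ws)
    fn$v <- combine("v", f0, fs, inc$rv, w0, ws)
    fn$w <- combine("w", f0, fs, inc$rw, w0, ws)
    if (!is.null(sim$assembly))
      fn$phi <- clamp_angles(w0 * f0$phi + ws * (fs$phi + dt * inc$rates))
    if (has_scalar)
      fn$C <- clipC(w0 * f0$C + ws * (fs$C + dt * inc$rC))
    if (!is.null(inc$rates)) fn$rates <- inc$rates
    ## sponge: the tube surrogates end at the open top face; strong damping
    ## of the tangential velocity in the top layers keeps the reservoir
    ## inflow plug-like and suppresses open-boundary reflections
    if (!is.null(sim$assembly)) {
      ks <- max(1L, g$nz - 2L):g$nz
      damp <- exp(-(sim$sponge_sigma %||% 300) * dt)
      fn$u[, , ks] <- damp * fn$u[, , ks]
      fn$v[, , ks] <- damp * fn$v[, , ks]
    }
    rt <- retag_at(fn, sim, t_target)
    tag <<- rt$tag; av <<- rt$av
    fn <- force_and_project(fn, sim, rt$tag, dt)
    if (has_scalar && !is.null(rt$tag))
      fn$C <- array(extend_scalar(fn$C, rt$tag$mask, g$nx, g$ny, g$nz),
                    dim(fn$C))
    fn
  }
  sim$av <- av
  f1 <- stage(f0, 0, 1, flow$t + dt)
  sim$av <- av
  f2 <- stage(f1, 3 / 4, 1 / 4, flow$t + dt / 2)
  sim$av <- av
  f3 <- stage(f2, 1 / 3, 2 / 3, flow$t + dt)
  f3$t <- flow$t + dt
  if (any(!is.finite(f3$u)) || any(!is.finite(f3$w)))
    stop("divergence error: non-finite velocity detected")
  list(flow = f3, tag = tag, av = av)
}

#' Run a full simulation of one or more heartbeats
#'
#' Orchestrates the coupled system from rest at end-diastole: the prescribed
#' ventricular volume waveform drives the wall, the valve angles follow the
#' flow, the aortic orifice opens and closes, and (optionally) a passive
#' marker is released at end-systole to measure washout. Flow metrics are
#' recorded at every step.
#'
#' @param config a validated [run_config()] list.
#' @param progress if `TRUE`, log one line per step to stderr.
#' @return An object of class `simulation_result`: `series` (per-step metric
#'   data frame), `report` ([metric_report()] over the last full cycle),
#'   `flow`, `grid`, `assembly`, `config`, `Vresidual` (fraction or `NA`).
#' @export
run_cycle <- function(config, progress = FALSE) {
  cfg <- run_config(config)
  preset <- lv_preset(cfg$lv_preset, period = cfg$period)
  lv <- make_lv_surface(preset$shape_params, preset$waveform,
                        cfg$lv_n_theta, cfg$lv_n_s)
  fam <- make_mv_family(cfg$mv_preset, cfg$severity,
                        cfg$mv_n_theta, cfg$mv_n_s)
  assembly <- compose_domain(lv, fam, list(radius = cfg$aortic_radius))
  grid <- build_grid(assembly$box, cfg$nx, cfg$ny, cfg$nz)
  wf <- preset$waveform
  sim <- list(grid = grid, assembly = assembly, nu = cfg$nu,
              kappa = cfg$kappa, zper = FALSE, scalar_active = FALSE,
              cfl_max = cfg$cfl_max, phi_closed_tol = cfg$phi_closed_tol,
              poisson_rtol = cfg$poisson_rtol,
              poisson_maxit = cfg$poisson_maxit,
              valve_rate_max = cfg$valve_rate_max,
              upwind_blend = cfg$upwind_blend,
              waveform = wf,
              av = list(open = FALSE))
  sim$phi_res <- resolved_opening_angle(fam, grid)
  flow <- empty_flow(grid)
  ## start from rest at end-systole: valve closed, aortic valve closed; the
  ## E-wave then opens the valve and systolic flow reversal closes it
  t0 <- wf$t_end_systole
  flow$t <- t0
  flow$phi <- c(0, 0)
  flow$rates <- c(0, 0)
  ## effective orifice area of the closed valve (structural, static)
  EOA <- mvo_area(extract_orifice(interpolate_valve(fam, 0, 0)))
  t_end <- t0 + cfg$n_cycles * cfg$period
  if (cfg$end_time > 0) t_end <- min(t_end, cfg$end_time)
  if (cfg$n_cycles == 0)
    return(structure(list(series = NULL, report = NULL, flow = flow,
                          grid = grid, assembly = assembly, config = cfg,
                          Vresidual = NA, EOA = EOA),
                     class = "simulation_result"))
  rt <- retag_at(flow, sim, t0)
  tag <- rt$tag; sim$av <- rt$av
  t_mark <- if (cfg$mark_cycle > 0)
    t0 + (cfg$mark_cycle - 1) * cfg$period else Inf
  t_measure <- t_mark + cfg$period
  Vresidual <- NA
  marked_vol <- NA   # discrete marked volume (removes the O(h) cut-cell
                     # bias from the washout normalization)
  cellvol <- grid$hx * grid$hy * grid$hz
  if (is.finite(t_mark) && t_mark <= t0 + 1e-12) {
    flow$C <- init_marker(flow, tag, grid)
    marked_vol <- sum(flow$C) * cellvol
    sim$scalar_active <- TRUE
  }
  rows <- list(); irow <- 0; istep <- 0L
  while (flow$t < t_end - 1e-12) {
    g <- grid
    rate <- max_cfl_rate(flow$u, flow$v, flow$w, g$nx, g$ny, g$nz,
                         g$hx, g$hy, g$hz)
    brate <- max(abs(tag$bu) / g$hx + abs(tag$bv) / g$hy +
                   abs(tag$bw) / g$hz)
    dt <- min(cfg$dt_max, 0.9 * cfg$cfl_max / max(rate, brate, 1e-9))
    if (dt < 1e-7)
      stop("divergence error: time step collapsed (unstable run)")
    ## land exactly on marking / measurement / end times
    for (tstop in c(t_mark, t_measure, t_end))
      if (flow$t < tstop - 1e-12) dt <- min(dt, tstop - flow$t)
    stepped <- advance(flow, sim, dt, tag)
    flow <- stepped$flow; tag <- stepped$tag; sim$av <- stepped$av
    ## passive-marker events
    if (is.finite(t_mark) && !sim$scalar_active &&
        flow$t >= t_mark - 1e-12) {
      flow$C <- init_marker(flow, tag, grid)
      marked_vol <- sum(flow$C) * cellvol
      sim$scalar_active <- TRUE
    }
    if (sim$scalar_active && is.na(Vresidual) &&
        flow$t >= t_measure - 1e-12)
      Vresidual <- residual_volume(flow$C, tag$mask, grid, marked_vol)
    ## metric series row (optionally thinned; the integrals below use the
    ## recorded samples trapezoidally)
    istep <- istep + 1L
    if (istep %% cfg$metric_every == 0L ||
        flow$t >= t_end - 1e-12 ||
        abs(flow$t - t_mark) < 1e-12 || abs(flow$t - t_measure) < 1e-12) {
      irow <- irow + 1
      rows[[irow]] <- metric_row(flow, sim, tag, wf)
    }
    if (!is.null(cfg$output_dir) && cfg$snapshot_every > 0L &&
        istep %% cfg$snapshot_every == 0L) {
      dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
      write_vtk_snapshot(flow, grid, tag,
                         file.path(cfg$output_dir,
                                   sprintf("snapshot_%06d.vtk", irow)))
    }
    if (progress && istep %% 25L == 0L)
      message(sprintf(
        "t=%.4f dt=%.2e CFL=%.2f phi=(%.2f, %.2f) AV=%d QMV=%.2f",
        flow$t, dt, rate * dt, flow$phi[1], flow$phi[2],
        as.integer(sim$av$open), rows[[irow]]$QMV))
  }
  series <- do.call(rbind, rows)
  report <- report_from_series(series, wf, assembly, EOA, Vresidual,
                               cycle = cfg$n_cycles, t_origin = t0)
  structure(list(series = series, report = report, flow = flow, grid = grid,
                 assembly = assembly, config = cfg, Vresidual = Vresidual,
                 EOA = EOA),
            class = "simulation_result")
}

## one row of the per-step metric series
metric_row <- function(flow, sim, tag, wf) {
  g <- sim$grid; asm <- sim$assembly
  st <- valve_state(flow$phi[1], flow$phi[2], flow$rates[1], flow$rates[2])
  vs <- valve_surfaces_at(asm$mv, st)
  orif <- extract_orifice(vs)
  vsamp <- flow_sampler(flow, g)
  csamp <- scalar_sampler(flow, g)
  mvo <- mvo_area(orif)
  qmv <- orifice_flow(vsamp, orif)
  qmvold <- if (isTRUE(sim$scalar_active))
    orifice_flow(vsamp, orif, weight = csamp) else 0
  qmva <- annulus_flow(vsamp, asm$tubes$atrium$center,
                       asm$tubes$atrium$radius, normal = c(0, 0, 1))
  qlv <- annulus_flow(vsamp, c(0, 0, 0), asm$basal$outer_radius,
                      normal = c(0, 0, -1))
  data.frame(t = flow$t, MVO = mvo, QMV = qmv, QMVa = qmva, QLV = qlv,
             QMVold = qmvold, dVdt = wf$dvdt(flow$t),
             phi1 = flow$phi[1], phi2 = flow$phi[2],
             dphi1 = flow$rates[1], dphi2 = flow$rates[2],
             AV_open = isTRUE(sim$av$open),
             Cmin = if (isTRUE(sim$scalar_active)) min(flow$C) else NA,
             Cmax = if (isTRUE(sim$scalar_active)) max(flow$C) else NA,
             phase = phase_of(wf, flow$t))
}

## cycle-integrated report from the recorded series (last full cycle)
report_from_series <- function(series, wf, assembly, EOA, Vresidual,
                               cycle = 1, t_origin = wf$t_end_systole) {
  t0 <- t_origin + (cycle - 1) * wf$period
  win <- series[series$t > t0 + 1e-12 &
                  series$t <= t0 + wf$period + 1e-9, ]
  if (nrow(win) < 3) return(NULL)
  ## a truncated run may not cover both phases; report nothing in that case
  phases <- unique(phase_of(wf, (win$t[-1] + win$t[-nrow(win)]) / 2))
  if (!all(c("systole", "diastole") %in% phases)) return(NULL)
  Vreg <- integrate_phase(win, "systole", "QMV", wf)
  VregMVa <- integrate_phase(win, "systole", "QMVa", wf)
  VLVa <- integrate_phase(win, "diastole", "QLV", wf)
  Vregold <- integrate_phase(win, "systole", "QMVold", wf)
  metric_report(MVA = assembly$mv$MVA, EOA = EOA, SV = wf$SV,
                VregMVa = VregMVa, Vreg = Vreg, VLVa = VLVa,
                Vresidual = Vresidual, Vregold = Vregold)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %s LV + %s MV (severity %.2f), %d steps\n",
              x$config$lv_preset, x$config$mv_preset, x$config$severity,
              if (is.null(x$series)) 0L else nrow(x$series)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}


## smallest opening angle at which the inter-leaflet aperture is resolved by
## the grid (median trailing-edge gap of at least ~1.5 cells)
resolved_opening_angle <- function(family, grid) {
  hmax <- max(grid$hx, grid$hy, grid$hz)
  for (phi in seq(0.05, pi / 2, by = 0.05)) {
    o <- extract_orifice(interpolate_valve(family, phi, phi))
    if (stats::median(o$gap) >= 1.5 * hmax) return(phi)
  }
  pi / 2
}
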