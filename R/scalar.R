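#' Initialize the passive blood marker at end-systole
#'
#' Sets the concentration to 1 in every fluid cell of the ventricular cavity
#' below the basal plane (the blood present in the LV at end-systole) and to
#' 0 elsewhere (tubes, atrium, aorta). Boundary and exterior cells are
#' excluded.
#'
#' @param flow flow state (for its grid-shaped scalar array and time).
#' @param tag cell classification from [tag_immersed_cells()].
#' @param grid a [build_grid()] grid.
#' @return the initialized concentration array.
#' @export
init_marker <- function(flow, tag, grid) {
  C <- array(0, dim(flow$C))
  cc <- cell_centers(grid)
  below <- rep(cc$z < 0, each = grid$nx * grid$ny)
  dim(below) <- dim(C)
  C[below & tag$mask == 0L] <- 1
  C
}

#' Advance the passive scalar alone by one time step
#'
#' SSP RK3 update of the advection-diffusion equation for the concentration
#' with a minmod-limited second-order advection scheme and explicit
#' diffusion, holding the velocity field fixed. Values are clipped to
#' `[0, 1]`. (During coupled runs the scalar is advanced inside [advance()]
#' with the same stages; this entry point serves transport verification and
#' standalone use.)
#'
#' @param C concentration array.
#' @param flow flow state providing `u`, `v`, `w`.
#' @param grid a [build_grid()] grid.
#' @param dt time step (s).
#' @param kappa diffusivity (cm^2/s).
#' @param mask optional cell classification (default: all fluid).
#' @param zper fully periodic in z (verification mode).
#' @return the advanced concentration array.
#' @export
advance_scalar <- function(C, flow, grid, dt, kappa, mask = NULL,
                           zper = FALSE) {
  g <- grid
  if (is.null(mask)) mask <- array(0L, c(g$nx, g$ny, g$nz))
  rate <- max_cfl_rate(flow$u, flow$v, flow$w, g$nx, g$ny, g$nz,
                       g$hx, g$hy, g$hz)
  if (rate * dt > 0.9) stop("CFL violation in scalar step")
  rhs <- function(Cs)
    array(scalar_rhs(Cs, flow$u, flow$v, flow$w, mask,
                     g$nx, g$ny, g$nz, g$hx, g$hy, g$hz, kappa,
                     as.integer(zper)), dim(Cs))
  clip <- function(x) pmin(pmax(x, 0), 1)
  C1 <- clip(C + dt * rhs(C))
  C2 <- clip(0.75 * C + 0.25 * (C1 + dt * rhs(C1)))
  clip(C / 3 + 2 / 3 * (C2 + dt * rhs(C2)))
}

#' Ventricular residual volume fraction
#'
#' The fraction of the marked (pre-diastolic) blood still inside the
#' ventricle: the concentration integrated over the fluid cells of the LV
#' cavity (below the basal plane), normalized by the end-systolic volume.
#'
#' @param C concentration array.
#' @param mask cell classification array.
#' @param grid a [build_grid()] grid.
#' @param ESV end-systolic volume (cm^3).
#' @return fraction in `[0, 1]`.
#' @export
residual_volume <- function(C, mask, grid, ESV) {
  cc <- cell_centers(grid)
  below <- rep(cc$z < 0, each = grid$nx * grid$ny)
  dim(below) <- dim(C)
  vol <- sum(C[below & mask == 0L]) * grid$hx * grid$hy * grid$hz
  min(max(vol / ESV, 0), 1)
}
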