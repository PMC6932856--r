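#' Valve state: opening angles and rates
#'
#' @param phi1,phi2 anterior / posterior opening angles (rad, clamped to
#'   `[0, pi/2]`).
#' @param dphi1,dphi2 angular rates (rad/s).
#' @return An object of class `valve_state`.
#' @export
valve_state <- function(phi1 = pi / 2, phi2 = pi / 2, dphi1 = 0, dphi2 = 0) {
  structure(list(phi1 = min(max(phi1, 0), pi / 2),
                 phi2 = min(max(phi2, 0), pi / 2),
                 dphi1 = dphi1, dphi2 = dphi2),
            class = "valve_state")
}

## memoized store for leaflet quadrature (the angles sit at their clamps
## for most of the cycle, so repeated evaluations are common)
.quad_cache <- new.env(parent = emptyenv())

## facet-level quadrature data for one leaflet at the current angles:
## centroids, unit normals, areas, and BOTH angle-derivative fields at facet
## centroids (each obtained by central finite differences of the leaflet
## positions in the corresponding angle; the non-associated one comes out
## identically zero because the leaflets are independent)
leaflet_quadrature <- function(family, phi1, phi2, which, h = 1e-3) {
  key <- paste(family$preset, family$severity, family$center[1],
               family$n_theta, family$n_s, phi1, phi2, which, h,
               sep = "|")
  hit <- .quad_cache[[key]]
  if (!is.null(hit)) return(hit)
  surf <- interpolate_valve(family, phi1, phi2)
  leaf <- if (which == 1) surf$anterior else surf$posterior
  fac <- surface_facets(leaf)
  tri <- surface_triangles(leaf)
  pick <- function(s) if (which == 1) s$anterior else s$posterior
  fd <- function(angle) {
    phi <- if (angle == 1) phi1 else phi2
    hp <- min(h, pi / 2 - phi); hm <- min(h, phi)
    args_p <- if (angle == 1) list(family, phi + hp, phi2)
              else list(family, phi1, phi + hp)
    args_m <- if (angle == 1) list(family, phi - hm, phi2)
              else list(family, phi1, phi - hm)
    sp <- pick(do.call(interpolate_valve, args_p))
    sm <- pick(do.call(interpolate_valve, args_m))
    cbind(as.vector(sp$x - sm$x), as.vector(sp$y - sm$y),
          as.vector(sp$z - sm$z)) / (hp + hm)
  }
  at_centroids <- function(dmat)
    (dmat[tri[, 1], , drop = FALSE] + dmat[tri[, 2], , drop = FALSE] +
       dmat[tri[, 3], , drop = FALSE]) / 3
  keep <- fac$area > 1e-14
  nunit <- fac$normal[keep, , drop = FALSE] / fac$area[keep]
  out <- list(centroid = fac$centroid[keep, , drop = FALSE], normal = nunit,
              area = fac$area[keep],
              dphi1 = at_centroids(fd(1))[keep, , drop = FALSE],
              dphi2 = at_centroids(fd(2))[keep, , drop = FALSE])
  if (length(ls(.quad_cache)) > 400) rm(list = ls(.quad_cache),
                                        envir = .quad_cache)
  .quad_cache[[key]] <- out
  out
}

#' Assemble the 2 x 2 least-squares system for the leaflet opening rates
#'
#' The flow-driven valve moves so that the leaflet velocity matches the fluid
#' velocity component normal to the leaflet surface, in the least-squares
#' sense over the valvular surface. The resulting normal equations are
#' `M[i,j] = int (dX/dphi_i . n)(dX/dphi_j . n) dA` and
#' `b[i] = int (v . n)(dX/dphi_i . n) dA`, integrated by one-point (centroid)
#' facet quadrature over both leaflets. The off-diagonal entries are computed
#' (not assumed zero); they vanish for this two-leaflet family because the two
#' derivative fields have disjoint support.
#'
#' @param family a [make_mv_family()] object.
#' @param state a [valve_state()].
#' @param fluid_sampler function taking an `n x 3` matrix of points (cm) and
#'   returning an `n x 3` matrix of fluid velocities (cm/s).
#' @param normal_offset sampling offset (cm): when positive, the fluid
#'   velocity at a quadrature point is the average of samples taken at
#'   `+offset` and `-offset` along the local normal. On a grid-based sampler
#'   this avoids re-reading the leaflet's own forced velocity from cut cells;
#'   zero samples exactly on the surface.
#' @return list with `M` (2 x 2, cm^4) and `b` (length 2, cm^4/s).
#' @export
assemble_system <- function(family, state, fluid_sampler, normal_offset = 0) {
  M <- matrix(0, 2, 2); b <- c(0, 0)
  for (leaf in 1:2) {
    q <- leaflet_quadrature(family, state$phi1, state$phi2, leaf)
    g1 <- rowSums(q$dphi1 * q$normal)
    g2 <- rowSums(q$dphi2 * q$normal)
    v <- if (normal_offset > 0)
      (fluid_sampler(q$centroid + normal_offset * q$normal) +
         fluid_sampler(q$centroid - normal_offset * q$normal)) / 2
    else fluid_sampler(q$centroid)
    vn <- rowSums(v * q$normal)
    M[1, 1] <- M[1, 1] + sum(g1 * g1 * q$area)
    M[2, 2] <- M[2, 2] + sum(g2 * g2 * q$area)
    M[1, 2] <- M[1, 2] + sum(g1 * g2 * q$area)
    b[1] <- b[1] + sum(vn * g1 * q$area)
    b[2] <- b[2] + sum(vn * g2 * q$area)
  }
  M[2, 1] <- M[1, 2]
  list(M = M, b = b)
}

#' Solve the valve system for the opening-angle rates
#'
#' Degenerate directions (diagonal entry below `eps`) are frozen: the
#' corresponding rate is set to zero.
#'
#' @param system list with `M`, `b` from [assemble_system()].
#' @param eps regularization threshold (cm^4).
#' @return numeric length-2 rates (rad/s).
#' @export
solve_rates <- function(system, eps = 1e-10) {
  M <- system$M; b <- system$b
  keep <- which(diag(M) > eps)
  r <- c(0, 0)
  if (length(keep) == 2) r <- solve(M, b)
  else if (length(keep) == 1) r[keep] <- b[keep] / M[keep, keep]
  r
}

## one Euler substep of the angles with clamping to [0, pi/2]; clamping at 0
## realizes the chordae constraint (no opening toward the atrium)
clamp_angles <- function(phi) pmin(pmax(phi, 0), pi / 2)

#' Advance the valve state over one time step (SSP RK3)
#'
#' Uses the same third-order Runge-Kutta stage combinations as the flow
#' solver; after each stage the angles are clamped to `[0, pi/2]`.
#'
#' @param family a [make_mv_family()] object.
#' @param state a [valve_state()].
#' @param fluid_sampler see [assemble_system()]; called at each stage's
#'   angles.
#' @param dt time step (s).
#' @return the advanced [valve_state()].
#' @export
step_valve <- function(family, state, fluid_sampler, dt) {
  rates_at <- function(phi) {
    st <- valve_state(phi[1], phi[2])
    solve_rates(assemble_system(family, st, fluid_sampler))
  }
  p0 <- c(state$phi1, state$phi2)
  r0 <- rates_at(p0)
  p1 <- clamp_angles(p0 + dt * r0)
  r1 <- rates_at(p1)
  p2 <- clamp_angles(0.75 * p0 + 0.25 * (p1 + dt * r1))
  r2 <- rates_at(p2)
  p3 <- clamp_angles(p0 / 3 + 2 / 3 * (p2 + dt * r2))
  rfin <- rates_at(p3)
  valve_state(p3[1], p3[2], rfin[1], rfin[2])
}

#' Aortic valve open/close logic
#'
#' The aortic valve opens when the mitral valve is closed (both opening
#' angles below `phi_closed_tol`) and the average normal velocity at the
#' aortic orifice is directed toward the aorta; otherwise it is closed and
#' the solver treats the orifice as a no-slip wall patch.
#'
#' @param mv_state a [valve_state()].
#' @param mean_outflow_velocity area-averaged normal velocity at the aortic
#'   orifice (cm/s, positive toward the aorta).
#' @param phi_closed_tol angle (rad) below which a leaflet counts as closed.
#' @return list with logical field `open`.
#' @export
update_aortic_valve <- function(mv_state, mean_outflow_velocity,
                                phi_closed_tol = 0.02) {
  open <- mv_state$phi1 < phi_closed_tol && mv_state$phi2 < phi_closed_tol &&
    mean_outflow_velocity > 0
  list(open = open)
}
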