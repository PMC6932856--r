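#' Extract the inter-leaflet orifice geometry
#'
#' Takes the trailing-edge rows (s = 1) of the two leaflet surfaces, pairs
#' stations on the two edges by arclength-proportional matching, and builds
#' the midline curve, per-station gap width and local normal (perpendicular
#' to the midline tangent and to the gap vector, oriented toward the atrium,
#' +z).
#'
#' @param valve_surfaces list with `anterior`, `posterior`
#'   [structured_surface()]s (e.g. from [interpolate_valve()]).
#' @return An object of class `orifice_geometry`: matrices `edge_ant`,
#'   `edge_post`, `midline` (n x 3, cm), vectors `gap` (cm), `arclength`
#'   (cm, increasing), matrix `normal` (n x 3), and edge velocities
#'   `vel_ant`, `vel_post`.
#' @export
extract_orifice <- function(valve_surfaces) {
  edge_of <- function(s) {
    j <- ncol(s$x)
    cbind(s$x[, j], s$y[, j], s$z[, j])
  }
  vel_of <- function(s) {
    j <- ncol(s$x)
    cbind(s$vx[, j], s$vy[, j], s$vz[, j])
  }
  ea <- edge_of(valve_surfaces$anterior)
  ep <- edge_of(valve_surfaces$posterior)
  va <- vel_of(valve_surfaces$anterior)
  vp <- vel_of(valve_surfaces$posterior)
  ## align directions: posterior edge may run opposite to the anterior one
  if (sum((ea[1, ] - ep[1, ])^2) > sum((ea[1, ] - ep[nrow(ep), ])^2)) {
    ep <- ep[nrow(ep):1, , drop = FALSE]
    vp <- vp[nrow(vp):1, , drop = FALSE]
  }
  arc <- function(e) {
    d <- sqrt(rowSums((e[-1, , drop = FALSE] - e[-nrow(e), , drop = FALSE])^2))
    c(0, cumsum(d))
  }
  sa <- arc(ea); sp <- arc(ep)
  la <- sa[length(sa)]; lp <- sp[length(sp)]
  if (la < 1e-12 || lp < 1e-12) stop("degenerate trailing edge")
  if (la / lp > 3 || lp / la > 3)
    stop("edge pairing failed: trailing edges of grossly different length")
  ## resample the posterior edge at the anterior arclength fractions
  frac <- sa / la
  interp_rows <- function(e, s_from, s_to) {
    apply(e, 2, function(col) stats::approx(s_from, col, xout = s_to,
                                            rule = 2)$y)
  }
  ep2 <- interp_rows(ep, sp / lp, frac)
  vp2 <- interp_rows(vp, sp / lp, frac)
  mid <- (ea + ep2) / 2
  gapv <- ea - ep2
  gap <- sqrt(rowSums(gapv^2))
  sm <- arc(mid)
  ## midline tangent by central differences in arclength
  n <- nrow(mid)
  tg <- rbind(mid[2, ] - mid[1, ],
              mid[3:n, , drop = FALSE] - mid[1:(n - 2), , drop = FALSE],
              mid[n, ] - mid[n - 1, ])
  tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-14)
  nrm <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (gap[i] > 1e-8) {
      v <- c(tg[i, 2] * gapv[i, 3] - tg[i, 3] * gapv[i, 2],
             tg[i, 3] * gapv[i, 1] - tg[i, 1] * gapv[i, 3],
             tg[i, 1] * gapv[i, 2] - tg[i, 2] * gapv[i, 1])
    } else {
      ## coapting edges: fall back to the vertical direction projected
      ## orthogonal to the midline tangent
      v <- c(0, 0, 1) - tg[i, 3] * tg[i, ]
    }
    ln <- sqrt(sum(v^2))
    if (ln < 1e-14) v <- c(0, 0, 1) else v <- v / ln
    if (v[3] < 0) v <- -v                 # orient toward the atrium
    nrm[i, ] <- v
  }
  structure(list(edge_ant = ea, edge_post = ep2, midline = mid, gap = gap,
                 arclength = sm, normal = nrm, vel_ant = va, vel_post = vp2),
            class = "orifice_geometry")
}

#' Instantaneous mitral-valve orifice area
#'
#' Arclength quadrature (trapezoid) of the gap width between the leaflet
#' trailing edges along the midline curve. Evaluated on the closed
#' configuration this is the effective orifice area (EOA).
#'
#' @param orifice an [extract_orifice()] object.
#' @return area (cm^2).
#' @export
mvo_area <- function(orifice) {
  s <- orifice$arclength; g <- orifice$gap
  sum((g[-1] + g[-length(g)]) / 2 * diff(s))
}

## Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch)
gauss01 <- function(n) {
  if (n == 1) return(list(x = 0.5, w = 1))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  ev <- eigen(J, symmetric = TRUE)
  ord <- order(ev$values)
  list(x = (ev$values[ord] + 1) / 2, w = ev$vectors[1, ord]^2)
}

#' Flow rate through the inter-leaflet orifice
#'
#' Implements the orifice flux: per midline station the fluid velocity is
#' averaged along the gap segment (Gauss points between the two facing
#' edges), the edge velocity is subtracted, the relative velocity is
#' projected on the station normal, weighted by the gap width and integrated
#' along the midline. Positive flux is directed toward the atrium
#' (regurgitant).
#'
#' @param fluid_sampler function mapping an `n x 3` point matrix to an
#'   `n x 3` velocity matrix.
#' @param orifice an [extract_orifice()] object.
#' @param n_gauss Gauss points per gap segment (>= 1).
#' @param edge_velocity `"mean"` (default) subtracts the mean of the two edge
#'   velocities; `"half_diff"` subtracts half the difference (the literal
#'   reading of the edge-motion term).
#' @param weight optional function mapping an `n x 3` point matrix to scalar
#'   weights (used for concentration-weighted fluxes).
#' @return flow rate (cm^3/s).
#' @export
orifice_flow <- function(fluid_sampler, orifice, n_gauss = 5,
                         edge_velocity = c("mean", "half_diff"),
                         weight = NULL) {
  edge_velocity <- match.arg(edge_velocity)
  n <- nrow(orifice$midline)
  gq <- gauss01(n_gauss)
  ## sample all stations x all gauss points in one call
  pts <- NULL
  for (g in gq$x)
    pts <- rbind(pts, orifice$edge_post + g * (orifice$edge_ant -
                                                 orifice$edge_post))
  v <- fluid_sampler(pts)
  wgt <- if (is.null(weight)) rep(1, nrow(pts)) else weight(pts)
  vn <- rowSums(v * orifice$normal[rep(seq_len(n), n_gauss), , drop = FALSE])
  vnw <- vn * wgt
  dim(vnw) <- c(n, n_gauss); dim(wgt) <- c(n, n_gauss)
  vbar <- as.vector(vnw %*% gq$w)          # gauss average of (v.n) * weight
  wbar <- as.vector(wgt %*% gq$w)
  ve <- switch(edge_velocity,
               mean = (orifice$vel_ant + orifice$vel_post) / 2,
               half_diff = (orifice$vel_ant - orifice$vel_post) / 2)
  ven <- rowSums(ve * orifice$normal)
  integrand <- (vbar - ven * wbar) * orifice$gap
  s <- orifice$arclength
  sum((integrand[-1] + integrand[-n]) / 2 * diff(s))
}

#' Flow rate through a planar annulus patch
#'
#' Area quadrature of the relative normal velocity over a horizontal disc
#' (used for both the mitral-annulus flux and the ventricular-annulus flux).
#'
#' @param fluid_sampler function mapping points to velocities.
#' @param center disc center (cm).
#' @param radius disc radius (cm).
#' @param normal unit normal (sign fixes the positive flux direction).
#' @param annulus_velocity mean velocity of the annulus itself (cm/s).
#' @param nr,nt radial / azimuthal quadrature resolution.
#' @return flow rate (cm^3/s).
#' @export
annulus_flow <- function(fluid_sampler, center, radius,
                         normal = c(0, 0, 1), annulus_velocity = c(0, 0, 0),
                         nr = 24, nt = 48) {
  ## midpoint rule in r^2 and theta (uniform-area cells)
  r <- radius * sqrt((seq_len(nr) - 0.5) / nr)
  th <- 2 * pi * (seq_len(nt) - 0.5) / nt
  pts <- cbind(as.vector(outer(r, cos(th))) + center[1],
               as.vector(outer(r, sin(th))) + center[2],
               center[3])
  v <- fluid_sampler(pts)
  vrel <- sweep(v, 2, annulus_velocity)
  dA <- pi * radius^2 / (nr * nt)
  sum(vrel %*% normal) * dA
}

#' Integrate a flux trace over a cardiac phase
#'
#' Trapezoidal time integration restricted to the systolic or diastolic
#' window; each sampling interval is assigned to a phase by the sign of
#' dV/dt at its midpoint.
#'
#' @param series data frame with a time column `t` and flux columns
#'   (cm^3/s).
#' @param phase `"systole"` or `"diastole"`.
#' @param flux name of the flux column to integrate.
#' @param waveform the [volume_waveform()] defining the phases.
#' @return integrated volume (cm^3).
#' @export
integrate_phase <- function(series, phase = c("systole", "diastole"), flux,
                            waveform) {
  phase <- match.arg(phase)
  t <- series$t; q <- series[[flux]]
  if (length(t) < 2) stop("phase window empty")
  mid <- (t[-1] + t[-length(t)]) / 2
  keep <- phase_of(waveform, mid) == phase
  if (!any(keep)) stop("phase window empty")
  contrib <- (q[-1] + q[-length(q)]) / 2 * diff(t)
  sum(contrib[keep])
}

#' Assemble the cycle-integrated regurgitation report
#'
#' Computes every derived quantity from the raw inputs: the false
#' regurgitation identity `Vregfalse = VregMVa - Vreg`, the normalized
#' percentages, and the residual of the proportionality between the
#' regurgitant fraction of the stroke volume and the normalized effective
#' orifice area.
#'
#' @param MVA mitral valve area (cm^2).
#' @param EOA effective orifice area (cm^2).
#' @param SV stroke volume (cm^3).
#' @param VregMVa total (annulus) regurgitant volume (cm^3).
#' @param Vreg orifice regurgitant volume (cm^3).
#' @param VLVa diastolic volume through the ventricular annulus (cm^3).
#' @param Vresidual residual-volume fraction of ESV (0..1 scale), or `NA`.
#' @param Vregold old-blood regurgitant volume (cm^3), or `NA`.
#' @return An object of class `metric_report` (a list of named numbers).
#' @export
metric_report <- function(MVA, EOA, SV, VregMVa, Vreg, VLVa = NA,
                          Vresidual = NA, Vregold = NA) {
  rep <- list(
    MVA = MVA, EOA = EOA, EOA_MVA_pct = 100 * EOA / MVA,
    SV = SV,
    VregMVa = VregMVa,
    Vregfalse = VregMVa - Vreg,
    Vreg = Vreg,
    Vreg_SV_pct = 100 * Vreg / SV,
    VLVa = VLVa,
    Vresidual_pct = 100 * Vresidual,
    Vregold = Vregold,
    Vregold_Vreg_pct = if (is.na(Vregold) || Vreg <= 0) NA
                       else 100 * Vregold / Vreg)
  rep$eoa_prop_residual <- abs(rep$Vreg_SV_pct - rep$EOA_MVA_pct)
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report\n")
  cat(sprintf("  MVA %.2f cm2   EOA %.3f cm2   EOA/MVA %.1f%%\n",
              x$MVA, x$EOA, x$EOA_MVA_pct))
  cat(sprintf("  SV %.2f cm3   VregMVa %.2f   Vregfalse %.2f   Vreg %.2f\n",
              x$SV, x$VregMVa, x$Vregfalse, x$Vreg))
  cat(sprintf("  Vreg/SV %.2f%%", x$Vreg_SV_pct))
  if (!is.na(x$Vresidual_pct))
    cat(sprintf("   Vresidual %.1f%%", x$Vresidual_pct))
  if (!is.na(x$Vregold))
    cat(sprintf("   Vregold %.2f (%.1f%% of Vreg)",
                x$Vregold, x$Vregold_Vreg_pct))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
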