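#' Synthetic mitral-valve family
#'
#' Builds the two-leaflet valve configuration family: a closed configuration
#' (leaflets form a coapting funnel below the annulus plane, optionally with a
#' localized coaptation defect emulating a posterior-leaflet prolapse) and an
#' open configuration (leaflets hanging toward the apex). Intermediate shapes
#' are produced by [interpolate_valve()] from two independent opening angles.
#'
#' The presets differ in annulus area (MVA) and in where the coaptation defect
#' sits on the posterior leaflet: `healthy` has a broad, shallow central
#' defect (severity 0 gives perfect coaptation), `P3like` a defect near the
#' posteromedial commissure, `P2like` one at the middle scallop. The defect
#' amplitude scales continuously with `severity`, so the closed-valve orifice
#' area grows continuously from zero; the annulus is identical across
#' severities.
#'
#' @param preset one of `"healthy"`, `"P3like"`, `"P2like"`.
#' @param severity coaptation-defect amplitude in `[0, 1]`; 0 = full
#'   coaptation.
#' @param n_theta nodes along each leaflet's annulus arc (>= 8).
#' @param n_s nodes from annulus to trailing edge (>= 4).
#' @param center annulus center (cm), length-3; annulus lies in the z = 0
#'   plane.
#' @return An object of class `valve_family` with fields `open_config`,
#'   `closed_config` (lists with `anterior`, `posterior`
#'   [structured_surface()]s), `annulus_curve`, `MVA`, `radius`, `center`,
#'   `hinge` (point + direction of the commissural axis), `preset`,
#'   `severity`.
#' @export
make_mv_family <- function(preset = c("healthy", "P3like", "P2like"),
                           severity = 0, n_theta = 24L, n_s = 8L,
                           center = c(0, 0, 0)) {
  preset <- match.arg(preset)
  stopifnot(severity >= 0, severity <= 1, n_theta >= 8L, n_s >= 4L)
  MVA <- switch(preset, healthy = 6.20, P3like = 4.83, P2like = 4.26)
  rm <- sqrt(MVA / pi)
  ## defect location/width/amplitude on the posterior arc (theta in
  ## [pi/2, 3pi/2], measured from the +x anterior direction)
  defect <- switch(preset,
    healthy = list(theta0 = pi, sigma = 0.90, amp = 0.35),
    P3like  = list(theta0 = pi / 2 + 0.55, sigma = 0.35, amp = 1.30),
    P2like  = list(theta0 = pi, sigma = 0.55, amp = 1.00))
  depth <- 0.7 * rm                     # coaptation depth below the annulus
  re <- 0.95 * rm                       # trailing-edge half-span
  gap_dir <- c(-1, 0, 0.6); gap_dir <- gap_dir / sqrt(sum(gap_dir^2))
  s <- seq(0, 1, length.out = n_s + 1L)

  build_leaflet <- function(th, prolapse) {
    ## annulus arc and closed trailing edge
    ax <- center[1] + rm * cos(th); ay <- center[2] + rm * sin(th)
    az <- rep(center[3], length(th))
    ex <- rep(center[1], length(th)); ey <- center[2] + re * sin(th)
    ez <- rep(center[3] - depth, length(th))
    q <- s                              # ruled blend annulus -> edge
    X <- outer(ax, 1 - q) + outer(ex, q)
    Y <- outer(ay, 1 - q) + outer(ey, q)
    Z <- outer(az, 1 - q) + outer(ez, q)
    closed <- list(x = X, y = Y, z = Z)
    if (prolapse && severity > 0) {
      g <- severity * defect$amp * exp(-((th - defect$theta0) / defect$sigma)^2)
      closed$x <- closed$x + outer(g, q) * gap_dir[1]
      closed$y <- closed$y + outer(g, q) * gap_dir[2]
      closed$z <- closed$z + outer(g, q) * gap_dir[3]
    }
    ## open configuration: preserve the closed chord length per station,
    ## hang from the annulus nearly apex-ward with a slight inward tilt
    len <- sqrt((ex - ax)^2 + (ey - ay)^2 + (ez - az)^2)
    ux <- (center[1] - ax) / rm; uy <- (center[2] - ay) / rm
    dx <- 0.3 * ux; dy <- 0.3 * uy; dz <- -1
    dn <- sqrt(dx^2 + dy^2 + dz^2)
    open <- list(
      x = outer(ax, rep(1, n_s + 1L)) + outer(len * dx / dn, q),
      y = outer(ay, rep(1, n_s + 1L)) + outer(len * dy / dn, q),
      z = outer(az, rep(1, n_s + 1L)) + outer(len * dz / dn, q))
    list(closed = closed, open = open)
  }

  th_ant <- seq(-pi / 2, pi / 2, length.out = n_theta + 1L)
  th_post <- seq(pi / 2, 3 * pi / 2, length.out = n_theta + 1L)
  ant <- build_leaflet(th_ant, prolapse = FALSE)
  post <- build_leaflet(th_post, prolapse = TRUE)
  as_ss <- function(p) structured_surface(p$x, p$y, p$z)
  th_full <- seq(0, 2 * pi, length.out = 2 * n_theta + 1L)
  annulus <- cbind(center[1] + rm * cos(th_full),
                   center[2] + rm * sin(th_full), center[3])
  structure(list(
    open_config = list(anterior = as_ss(ant$open),
                       posterior = as_ss(post$open)),
    closed_config = list(anterior = as_ss(ant$closed),
                         posterior = as_ss(post$closed)),
    annulus_curve = annulus, MVA = MVA, radius = rm, center = center,
    hinge = list(point = center, direction = c(0, 1, 0)),
    preset = preset, severity = severity,
    n_theta = as.integer(n_theta), n_s = as.integer(n_s)),
    class = "valve_family")
}

## rotate points about the hinge line by angle alpha (vectorized over rows)
rotate_about_hinge <- function(p, hinge, alpha) {
  ## hinge direction is the unit y axis in the valve frame
  rel <- sweep(p, 2, hinge$point)
  eta <- rel[, 2]
  px <- rel[, 1]; pz <- rel[, 3]
  ca <- cos(alpha); sa <- sin(alpha)
  cbind(hinge$point[1] + ca * px + sa * pz,
        hinge$point[2] + eta,
        hinge$point[3] - sa * px + ca * pz)
}

## per-node path from closed to open: rotation about the hinge line through
## the node's own closed->open swing angle, scaled by f, plus a linear blend
## of the residual displacement; endpoints are reproduced exactly
leaflet_at_fraction <- function(closed, open, hinge, f) {
  pc <- cbind(as.vector(closed$x), as.vector(closed$y), as.vector(closed$z))
  po <- cbind(as.vector(open$x), as.vector(open$y), as.vector(open$z))
  rc <- sweep(pc, 2, hinge$point); ro <- sweep(po, 2, hinge$point)
  ## swing angle in the plane normal to the hinge (x-z plane)
  cx <- rc[, 1]; cz <- rc[, 3]; ox <- ro[, 1]; oz <- ro[, 3]
  dot <- cx * ox + cz * oz
  crs <- cz * ox - cx * oz            # (rc x ro) . y
  alpha <- atan2(crs, dot)
  alpha[(cx^2 + cz^2) < 1e-16 | (ox^2 + oz^2) < 1e-16] <- 0
  rot_f <- rotate_about_hinge(pc, hinge, f * alpha)
  rot_1 <- rotate_about_hinge(pc, hinge, alpha)
  p <- rot_f + f * (po - rot_1)
  d <- dim(closed$x)
  structured_surface(matrix(p[, 1], d[1], d[2]),
                     matrix(p[, 2], d[1], d[2]),
                     matrix(p[, 3], d[1], d[2]))
}

#' Interpolate the valve configuration at given opening angles
#'
#' Angle 0 reproduces the closed configuration exactly, pi/2 the open one;
#' each leaflet follows its own angle independently along a
#' rotation-dominated, continuously differentiable path.
#'
#' @param family a [make_mv_family()] object.
#' @param phi1,phi2 anterior / posterior opening angles (rad, in `[0, pi/2]`).
#' @return list with `anterior`, `posterior` [structured_surface()]s.
#' @export
interpolate_valve <- function(family, phi1, phi2) {
  if (phi1 < 0 || phi1 > pi / 2 || phi2 < 0 || phi2 > pi / 2)
    stop("opening angles must lie in [0, pi/2]")
  f1 <- phi1 / (pi / 2); f2 <- phi2 / (pi / 2)
  if (f1 == 0) ant <- family$closed_config$anterior
  else if (f1 == 1) ant <- family$open_config$anterior
  else ant <- leaflet_at_fraction(family$closed_config$anterior,
                                  family$open_config$anterior,
                                  family$hinge, f1)
  if (f2 == 0) post <- family$closed_config$posterior
  else if (f2 == 1) post <- family$open_config$posterior
  else post <- leaflet_at_fraction(family$closed_config$posterior,
                                   family$open_config$posterior,
                                   family$hinge, f2)
  list(anterior = ant, posterior = post)
}

#' Derivative of the valve configuration with respect to an opening angle
#'
#' Central finite difference of [interpolate_valve()] in the angle, step
#' `h` rad. The derivative field is identically zero over the leaflet not
#' associated with the differentiated angle (the leaflets are independent).
#'
#' @param family a [make_mv_family()] object.
#' @param phi1,phi2 current opening angles (rad).
#' @param which 1 for the anterior angle, 2 for the posterior.
#' @param h finite-difference step (rad).
#' @return list with matrices `dx`, `dy`, `dz` over the associated leaflet's
#'   grid, and `leaflet` naming it.
#' @export
valve_config_derivative <- function(family, phi1, phi2, which = 1,
                                    h = 1e-3) {
  stopifnot(which %in% c(1, 2))
  phi <- if (which == 1) phi1 else phi2
  hp <- min(h, pi / 2 - phi); hm <- min(h, phi)
  ## one-sided at the interval ends, central otherwise
  if (hp + hm <= 0) stop("degenerate angle step")
  leafname <- if (which == 1) "anterior" else "posterior"
  eval_leaf <- function(p) {
    if (which == 1) interpolate_valve(family, p, phi2)$anterior
    else interpolate_valve(family, phi1, p)$posterior
  }
  sp <- eval_leaf(phi + hp); sm <- eval_leaf(phi - hm)
  d <- hp + hm
  list(dx = (sp$x - sm$x) / d, dy = (sp$y - sm$y) / d,
       dz = (sp$z - sm$z) / d, leaflet = leafname)
}

#' Valve leaflet surfaces with motion velocities at a valve state
#'
#' @param family a [make_mv_family()] object.
#' @param state a [valve_state()] (angles and angular rates).
#' @return list with `anterior`, `posterior` surfaces whose node velocities
#'   are `dX/dphi * dphi/dt`.
#' @export
valve_surfaces_at <- function(family, state) {
  surf <- interpolate_valve(family, state$phi1, state$phi2)
  d1 <- valve_config_derivative(family, state$phi1, state$phi2, which = 1)
  d2 <- valve_config_derivative(family, state$phi1, state$phi2, which = 2)
  surf$anterior$vx <- d1$dx * state$dphi1
  surf$anterior$vy <- d1$dy * state$dphi1
  surf$anterior$vz <- d1$dz * state$dphi1
  surf$posterior$vx <- d2$dx * state$dphi2
  surf$posterior$vy <- d2$dy * state$dphi2
  surf$posterior$vz <- d2$dz * state$dphi2
  surf
}

#' Severity producing a target effective orifice area
#'
#' Root-finds the coaptation-defect severity whose closed-valve orifice area
#' ([mvo_area()] of the closed configuration) matches `eoa`.
#'
#' @param preset valve preset name.
#' @param eoa target effective orifice area (cm^2).
#' @param ... passed to [make_mv_family()].
#' @return severity in `[0, 1]`.
#' @export
severity_for_eoa <- function(preset, eoa, ...) {
  f <- function(s) {
    fam <- make_mv_family(preset, severity = s, ...)
    mvo_area(extract_orifice(fam$closed_config)) - eoa
  }
  if (eoa <= 0) return(0)
  top <- f(1)
  if (top < 0) stop("target orifice area not reachable at severity 1")
  stats::uniroot(f, c(0, 1), tol = 1e-6)$root
}
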