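#' Synthetic left-ventricle geometry
#'
#' Builds a time-varying truncated-prolate-spheroid model of the LV endocardium
#' whose enclosed cavity volume tracks a prescribed volume waveform exactly (up
#' to surface-quadrature error). The base plane sits at z = 0 with the apex at
#' negative z; the basal ring radius is constant in time, contraction is
#' carried by an s-weighted scaling of the short semi-axes plus a small
#' long-axis shortening (a fixed 10% share of the volume change), which keeps
#' the annulus near-stationary as in imaging-derived ventricles.
#'
#' @param shape_params list with fields `c0` (half long-axis at EDV, cm),
#'   `cos_base` (cosine of the base truncation colatitude, in (0,1)), and
#'   optionally `gamma` (long-axis share of volume change, default 0.1).
#'   Use [lv_preset()] for the built-in healthy / dilated shapes.
#' @param waveform a [volume_waveform()].
#' @param n_theta,n_s grid resolution (>= 8 each); the stored grid carries
#'   `n_theta + 1` rows (theta seam duplicated) and `n_s + 1` columns.
#' @return An object of class `lv_geometry`; evaluate it at a time with
#'   [lv_surface_at()].
#' @export
make_lv_surface <- function(shape_params, waveform, n_theta = 64L, n_s = 32L) {
  stopifnot(inherits(waveform, "volume_waveform"),
            n_theta >= 8L, n_s >= 8L)
  c0 <- shape_params$c0
  beta <- shape_params$cos_base
  gamma <- if (is.null(shape_params$gamma)) 0.1 else shape_params$gamma
  stopifnot(c0 > 0, beta > 0, beta < 1)
  psi_b <- acos(beta)
  ## radial contraction weight w(s): zero at the base ring (annulus fixed),
  ## rising to one toward the apex; the quadratic rise leaves enough radial
  ## travel mid-cavity to realize low end-systolic volumes
  wfun <- function(s) 1 - (1 - s)^2
  ## cavity volume V = pi a0^2 c (I0 + 2 lam I1 + lam^2 I2)
  ## with Ik = int sin^3(psi) w^k dpsi over [psi_b, pi]
  s <- seq(0, 1, length.out = 4001L)
  psi <- psi_b + s * (pi - psi_b)
  ww <- wfun(s)
  simp <- function(f) {
    n <- length(f)
    h <- (pi - psi_b) / (n - 1)
    h / 3 * (f[1] + f[n] + 4 * sum(f[seq(2, n - 1, 2)]) +
               2 * sum(f[seq(3, n - 2, 2)]))
  }
  I0 <- simp(sin(psi)^3)
  I1 <- simp(sin(psi)^3 * ww)
  I2 <- simp(sin(psi)^3 * ww^2)
  a0 <- sqrt(waveform$EDV / (pi * c0 * I0))
  ## feasibility: the quadratic for the radial scale must have a real root
  ## across the whole volume range
  cmin <- c0 * (waveform$ESV / waveform$EDV)^gamma
  qmin <- waveform$ESV / (pi * a0^2 * cmin)
  if (I1^2 - I2 * (I0 - qmin) <= 0)
    stop("geometry infeasible: volume range too wide for this shape")
  structure(list(waveform = waveform, a0 = a0, c0 = c0, psi_b = psi_b,
                 beta = beta, gamma = gamma, I0 = I0, I1 = I1, I2 = I2,
                 wfun = wfun, n_theta = as.integer(n_theta),
                 n_s = as.integer(n_s)),
            class = "lv_geometry")
}

## radial scale lam(t) (= 1 + lambda') and long-axis c(t), with rates
lv_kinematics <- function(lv, t) {
  wf <- lv$waveform
  V <- wf$volume(t); Vd <- wf$dvdt(t)
  cc <- lv$c0 * (V / wf$EDV)^lv$gamma
  cd <- lv$gamma * cc * Vd / V
  Q <- V / (pi * lv$a0^2 * cc)
  Qd <- Vd / (pi * lv$a0^2 * cc) - Q * cd / cc
  disc <- lv$I1^2 - lv$I2 * (lv$I0 - Q)
  lamp <- (-lv$I1 + sqrt(disc)) / lv$I2
  lampd <- Qd / (2 * (lv$I1 + lv$I2 * lamp))
  list(c = cc, cdot = cd, lamp = lamp, lampdot = lampd)
}

#' Evaluate the LV endocardial surface at a time
#'
#' @param lv an `lv_geometry` from [make_lv_surface()].
#' @param t time (s).
#' @return A [structured_surface()] with analytic node velocities; the basal
#'   ring (s = 0 column) lies on z = 0.
#' @export
lv_surface_at <- function(lv, t) {
  kin <- lv_kinematics(lv, t)
  th <- seq(0, 2 * pi, length.out = lv$n_theta + 1L)
  s <- seq(0, 1, length.out = lv$n_s + 1L)
  psi <- lv$psi_b + s * (pi - lv$psi_b)
  w <- lv$wfun(s)
  Rrow <- lv$a0 * sin(psi) * (1 + kin$lamp * w)      # radius per s
  Rdot <- lv$a0 * sin(psi) * w * kin$lampdot
  zrow <- kin$c * (cos(psi) - lv$beta)
  zdot <- kin$cdot * (cos(psi) - lv$beta)
  ct <- cos(th); st <- sin(th)
  structured_surface(
    x = outer(ct, Rrow), y = outer(st, Rrow),
    z = matrix(rep(zrow, each = lv$n_theta + 1L), lv$n_theta + 1L),
    vx = outer(ct, Rdot), vy = outer(st, Rdot),
    vz = matrix(rep(zdot, each = lv$n_theta + 1L), lv$n_theta + 1L),
    closed_theta = TRUE)
}

#' Built-in ventricle presets
#'
#' `healthy` reproduces a normal ventricle (EDV 113.47, ESV 46.52 cm^3,
#' EF 59%); `dilated` a severe dilated cardiomyopathy (EDV 199.31,
#' ESV 142.50 cm^3, EF 29%).
#'
#' @param name `"healthy"` or `"dilated"`.
#' @param period heartbeat period (s).
#' @return list with `shape_params` and `waveform`, ready for
#'   [make_lv_surface()].
#' @export
lv_preset <- function(name = c("healthy", "dilated"), period = 1) {
  name <- match.arg(name)
  if (name == "healthy") {
    wf <- volume_waveform(EDV = 113.47, ESV = 46.52, period = period)
    sp <- list(c0 = 4.6, cos_base = 0.42)
  } else {
    wf <- volume_waveform(EDV = 199.31, ESV = 142.50, period = period)
    sp <- list(c0 = 5.2, cos_base = 0.42)
  }
  list(name = name, shape_params = sp, waveform = wf)
}

#' Basal ring radius of an LV geometry (constant in time)
#' @param lv an `lv_geometry`.
#' @export
lv_base_radius <- function(lv) lv$a0 * sin(lv$psi_b)

#' Apex depth (positive, cm) below the base plane at time t
#' @param lv an `lv_geometry`.
#' @param t time (s).
#' @export
lv_apex_depth <- function(lv, t) {
  kin <- lv_kinematics(lv, t)
  kin$c * (1 + lv$beta)
}


## axisymmetric cavity radius R(z) and wall velocity components at height z
## (z <= 0; vectorized over z); used by the cell tagger
lv_radius_profile <- function(lv, t, z) {
  kin <- lv_kinematics(lv, t)
  cosp <- pmin(pmax(z / kin$c + lv$beta, -1), 1)
  psi <- acos(cosp)
  psi <- pmax(psi, lv$psi_b)
  s <- (psi - lv$psi_b) / (pi - lv$psi_b)
  w <- lv$wfun(s)
  list(R = lv$a0 * sin(psi) * (1 + kin$lamp * w),
       vr = lv$a0 * sin(psi) * w * kin$lampdot,
       vz = kin$cdot * (cosp - lv$beta),
       z_apex = -kin$c * (1 + lv$beta))
}
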