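## polar structured disc surface in the z = plane, used for annulus-area
## quadrature and for exporting the basal plate
disc_surface <- function(center, radius, nr = 16L, nt = 48L) {
  th <- seq(0, 2 * pi, length.out = nt + 1L)
  r <- seq(0, radius, length.out = nr + 1L)
  r[1] <- 1e-6 * radius  # avoid a fully degenerate inner ring
  structured_surface(center[1] + outer(cos(th), r),
                     center[2] + outer(sin(th), r),
                     matrix(center[3], nt + 1L, nr + 1L),
                     closed_theta = TRUE)
}

translate_family <- function(family, offset) {
  for (cfg in c("open_config", "closed_config"))
    for (leaf in c("anterior", "posterior"))
      family[[cfg]][[leaf]] <- translate_surface(family[[cfg]][[leaf]], offset)
  family$annulus_curve <- sweep(family$annulus_curve, 2, -offset)
  family$center <- family$center + offset
  family$hinge$point <- family$hinge$point + offset
  family
}

#' Compose the full computational domain
#'
#' Places the mitral valve and the aortic orifice on the ventricular basal
#' plane (z = 0), closes the valvular plane with a basal plate spanning the
#' LV annulus minus the two orifices, and extends both orifices with straight
#' tube surrogates of atrium and aorta up to the top of the computational
#' box. The tubes only keep inflow and outflow separated above the valve
#' plane.
#'
#' @param lv an `lv_geometry` from [make_lv_surface()].
#' @param family a [make_mv_family()] object (built about the origin; it is
#'   translated to its basal-plane position).
#' @param aortic_params list with `radius` (cm, default 0.85).
#' @param box optional list of `x`, `y`, `z` ranges (cm); by default a box
#'   about 1.3x the LV bounding box plus tube headroom is used.
#' @return An object of class `domain_assembly`.
#' @export
compose_domain <- function(lv, family, aortic_params = list(radius = 0.85),
                           box = NULL) {
  rb <- lv_base_radius(lv)
  rm <- family$radius
  ra <- aortic_params$radius
  if (rm + ra >= 2 * rb)
    stop("layout error: orifices cannot fit inside the basal plane")
  ## centers along x: valve toward -x, aorta toward +x, margins ~10% of the
  ## available clearance
  xm <- -(rb - rm) * 0.94
  xa <- (rb - ra) * 0.94
  if ((xa - xm) <= (rm + ra))
    stop("layout error: mitral annulus and aortic orifice overlap")
  fam <- translate_family(family, c(xm, 0, 0))
  apex <- max(lv_apex_depth(lv, seq(0, lv$waveform$period, length.out = 41)))
  if (is.null(box)) {
    half <- 1.3 * max(rb, lv$a0 * 1.05)
    box <- list(x = c(-half, half), y = c(-half, half),
                z = c(-1.12 * apex, 2.0))
  }
  assembly <- structure(list(
    lv = lv, mv = fam,
    aortic = list(center = c(xa, 0, 0), radius = ra, normal = c(0, 0, 1)),
    basal = list(outer_radius = rb,
                 holes = list(mv = list(center = c(xm, 0, 0), radius = rm),
                              ao = list(center = c(xa, 0, 0), radius = ra))),
    tubes = list(atrium = list(center = c(xm, 0, 0), radius = rm),
                 aorta = list(center = c(xa, 0, 0), radius = ra)),
    box = box,
    basal_surface = disc_surface(c(0, 0, 0), rb),
    AMVa = surface_area(disc_surface(c(xm, 0, 0), rm, nr = 32L, nt = 96L)),
    ALVa = surface_area(disc_surface(c(0, 0, 0), rb, nr = 32L, nt = 96L))),
    class = "domain_assembly")
  assembly
}

#' @export
print.domain_assembly <- function(x, ...) {
  cat(sprintf(
    "domain_assembly: base radius %.2f cm, MVA %.2f cm2 at (%.2f, 0), aortic r %.2f cm at (%.2f, 0)\n",
    x$basal$outer_radius, x$mv$MVA, x$tubes$atrium$center[1],
    x$aortic$radius, x$aortic$center[1]))
  invisible(x)
}

#' Audit the geometric closure of a domain assembly
#'
#' Checks that the composed surfaces join watertightly: the LV basal ring
#' coincides with the basal-plate rim, each orifice ring lies on the basal
#' plane strictly inside the plate, the valve annulus coincides with the
#' atrium-tube foot, and the tubes reach the top box face exactly (tubes are
#' analytic cylinders spanning `[0, z_top]` by construction).
#'
#' @param assembly a [compose_domain()] object.
#' @param t time at which the LV ring is evaluated (s).
#' @return invisibly `TRUE`; stops with a description on failure.
#' @export
assembly_watertight <- function(assembly, t = 0) {
  lvs <- lv_surface_at(assembly$lv, t)
  ring <- cbind(lvs$x[, 1], lvs$y[, 1], lvs$z[, 1])
  rb <- assembly$basal$outer_radius
  if (max(abs(sqrt(ring[, 1]^2 + ring[, 2]^2) - rb)) > 1e-9 ||
      max(abs(ring[, 3])) > 1e-9)
    stop("LV basal ring does not match the basal plate rim")
  for (h in assembly$basal$holes) {
    if (sqrt(sum(h$center[1:2]^2)) + h$radius >= rb)
      stop("orifice ring extends beyond the basal plate")
  }
  ann <- assembly$mv$annulus_curve
  am <- assembly$tubes$atrium
  if (max(abs(sqrt((ann[, 1] - am$center[1])^2 +
                     (ann[, 2] - am$center[2])^2) - am$radius)) > 1e-9 ||
      max(abs(ann[, 3])) > 1e-9)
    stop("valve annulus does not match the atrium tube foot")
  invisible(TRUE)
}

## static per-grid tagging data (tube walls, basal plate, flood seeds),
## memoized per grid/assembly layout
.tag_cache <- new.env(parent = emptyenv())
tag_static_cache <- function(grid, assembly) {
  key <- paste(grid$nx, grid$ny, grid$nz,
               signif(c(grid$x0, grid$z0, grid$hx, grid$hz,
                        assembly$basal$outer_radius,
                        assembly$tubes$atrium$center[1],
                        assembly$tubes$atrium$radius,
                        assembly$tubes$aorta$radius), 10), collapse = "|")
  hit <- .tag_cache[[key]]
  if (!is.null(hit)) return(hit)
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  cc <- cell_centers(grid)
  xg <- rep(cc$x, times = ny); yg <- rep(cc$y, each = nx)
  delta <- 0.6 * sqrt(grid$hx^2 + grid$hy^2)
  kz_pos <- which(cc$z > 0)
  tube_idx <- integer(0)
  for (tube in assembly$tubes) {
    dc <- sqrt((xg - tube$center[1])^2 + (yg - tube$center[2])^2)
    ring2d <- which(abs(dc - tube$radius) <= delta)
    if (length(ring2d) && length(kz_pos))
      tube_idx <- c(tube_idx,
                    as.vector(outer(ring2d, (kz_pos - 1L) * nx * ny, `+`)))
  }
  kp <- which(cc$z > -grid$hz & cc$z < 0)
  if (length(kp) != 1L) stop("grid must place a cell-center layer in (-hz, 0)")
  hole_mv <- assembly$basal$holes$mv; hole_ao <- assembly$basal$holes$ao
  rr <- sqrt(xg^2 + yg^2)
  dmv <- sqrt((xg - hole_mv$center[1])^2 + (yg - hole_mv$center[2])^2)
  dao <- sqrt((xg - hole_ao$center[1])^2 + (yg - hole_ao$center[2])^2)
  plate2d <- which(rr <= assembly$basal$outer_radius + delta &
                     dmv > hole_mv$radius & dao > hole_ao$radius)
  ij_side <- which(xg == cc$x[1] | xg == cc$x[nx] |
                     yg == cc$y[1] | yg == cc$y[ny])
  seeds <- unique(c(seq_len(nx * ny),
                    as.vector(outer(ij_side,
                                    (seq_len(nz) - 1L) * nx * ny, `+`)))) - 1L
  cache <- list(cc = cc, xg = xg, yg = yg, rr2 = rr,
                tube_idx = unique(tube_idx),
                plate_idx = plate2d + (kp - 1L) * nx * ny,
                ao_idx = which(dao <= hole_ao$radius) + (kp - 1L) * nx * ny,
                seeds = seeds)
  .tag_cache[[key]] <- cache
  cache
}

#' Classify grid cells against the immersed geometry
#'
#' Rasterizes the LV wall and valve leaflet facets into the cell grid
#' (sampling each facet finer than the cell size), marks the analytic basal
#' plate, tube walls and (when closed) the aortic-orifice patch, then flood
#' fills the exterior from the box sides and bottom. Cells cut by a surface
#' are boundary cells carrying the local surface velocity, with priority
#' valve > basal plate > LV wall > tubes when a cell is cut by several
#' surfaces.
#'
#' @param grid a [build_grid()] grid.
#' @param assembly a [compose_domain()] object.
#' @param valve_surfaces leaflet surfaces with velocities (from
#'   [valve_surfaces_at()]).
#' @param t time (s), for the LV wall position and velocity.
#' @param av_open logical; when `FALSE` the aortic orifice is a wall patch.
#' @return list with integer array `mask` (0 fluid, 1 boundary, 2 exterior)
#'   and boundary-velocity arrays `bu`, `bv`, `bw` (cell-centered).
#' @export
tag_immersed_cells <- function(grid, assembly, valve_surfaces, t,
                               av_open = FALSE) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  n <- nx * ny * nz
  mask <- integer(n); prio <- integer(n)
  bu <- numeric(n); bv <- numeric(n); bw <- numeric(n)
  cache <- tag_static_cache(grid, assembly)
  mark_surface <- function(surf, priority) {
    fac <- surface_facets(surf)
    keep <- fac$area > 1e-14
    mark_facets(mask, prio, bu, bv, bw,
                fac$a[keep, , drop = FALSE], fac$b[keep, , drop = FALSE],
                fac$c[keep, , drop = FALSE],
                fac$velocity[keep, , drop = FALSE], as.integer(priority),
                nx, ny, nz, grid$x0, grid$y0, grid$z0,
                grid$hx, grid$hy, grid$hz)
  }
  cc <- cache$cc; xg <- cache$xg; yg <- cache$yg
  ## tube walls (priority 1), analytic vertical cylinders over z > 0
  idx <- cache$tube_idx
  if (length(idx)) {
    mask[idx] <- 1L; prio[idx] <- 1L
  }
  ## LV wall (priority 2): analytic center-based classification so the
  ## discrete wall straddles the true surface (a full-band rasterization
  ## would bias the cavity volume by O(h)); the boundary band is the set of
  ## outside cells face-adjacent to inside cells
  prof <- lv_radius_profile(assembly$lv, t, cc$z)
  inside <- matrix(FALSE, nx * ny, nz)
  for (k in seq_len(nz))
    if (cc$z[k] < 0 && cc$z[k] > prof$z_apex)
      inside[, k] <- cache$rr2 < prof$R[k]
  dim(inside) <- c(nx, ny, nz)
  ## 6-neighbour dilation (periodic wrap unnecessary: wall is interior)
  dil <- inside
  dil[-nx, , ] <- dil[-nx, , ] | inside[-1, , ]
  dil[-1, , ] <- dil[-1, , ] | inside[-nx, , ]
  dil[, -ny, ] <- dil[, -ny, ] | inside[, -1, ]
  dil[, -1, ] <- dil[, -1, ] | inside[, -ny, ]
  dil[, , -nz] <- dil[, , -nz] | inside[, , -1]
  dil[, , -1] <- dil[, , -1] | inside[, , -nz]
  dil[, , cc$z > 0] <- FALSE      # z >= 0 is owned by plate/tubes/orifices
  band <- which(as.vector(dil & !inside))
  if (length(band)) {
    upd <- band[prio[band] < 2L]
    if (length(upd)) {
      kk <- (upd - 1L) %/% (nx * ny) + 1L
      ij <- (upd - 1L) %% (nx * ny) + 1L
      th <- atan2(yg[ij], xg[ij])
      mask[upd] <- 1L; prio[upd] <- 2L
      bu[upd] <- prof$vr[kk] * cos(th)
      bv[upd] <- prof$vr[kk] * sin(th)
      bw[upd] <- prof$vz[kk]
    }
  }
  ## basal plate (priority 3): the cell layer just below z = 0
  idx <- if (av_open) cache$plate_idx else c(cache$plate_idx, cache$ao_idx)
  upd <- idx[prio[idx] < 3L]
  mask[upd] <- 1L; prio[upd] <- 3L
  ## valve leaflets (priority 4)
  if (!is.null(valve_surfaces)) {
    mark_surface(valve_surfaces$anterior, 4L)
    mark_surface(valve_surfaces$posterior, 4L)
  }
  ## exterior flood fill from the box sides and bottom
  flood_exterior(mask, cache$seeds, nx, ny, nz)
  ## leak audit: the mid-cavity and tube interiors must stay fluid
  probe <- function(p) {
    i <- pmin(pmax(1L, 1L + floor((p[1] - grid$x0) / grid$hx)), nx)
    j <- pmin(pmax(1L, 1L + floor((p[2] - grid$y0) / grid$hy)), ny)
    k <- pmin(pmax(1L, 1L + floor((p[3] - grid$z0) / grid$hz)), nz)
    mask[i + nx * (j - 1L) + nx * ny * (k - 1L)]
  }
  if (probe(c(0, 0, -0.45 * lv_apex_depth(assembly$lv, t))) == 2L ||
      probe(c(assembly$tubes$atrium$center[1], 0,
              assembly$box$z[2] - grid$hz / 2)) == 2L)
    stop("watertightness error: exterior leaked into the cavity")
  dim(mask) <- c(nx, ny, nz)
  dim(bu) <- c(nx, ny, nz); dim(bv) <- c(nx, ny, nz)
  dim(bw) <- c(nx, ny, nz)
  ## fluid connected components; components not reaching the open top face
  ## are sealed pockets (e.g. the ventricle while both valves are closed)
  labels <- array(label_fluid_components(mask, nx, ny, nz), c(nx, ny, nz))
  vented <- unique(as.vector(labels[, , nz]))
  sealed_ids <- setdiff(unique(as.vector(labels)), c(0L, vented))
  list(mask = mask, bu = bu, bv = bv, bw = bw,
       labels = labels, sealed_ids = sealed_ids)
}
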