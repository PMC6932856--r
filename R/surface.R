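#' Structured parametric surface
#'
#' A surface sampled on parametric coordinates (theta, s) stored as matrices of
#' 3D positions (cm) with optional per-node velocities (cm/s). Rows index the
#' circumferential coordinate theta, columns the longitudinal coordinate s.
#' Used for the ventricle wall, valve leaflets, the basal plate and the
#' atrium/aorta tube surrogates.
#'
#' @param x,y,z numeric matrices of node coordinates (cm), equal dimensions.
#' @param vx,vy,vz optional matrices of node velocities (cm/s); default zero.
#' @param closed_theta logical; if `TRUE` the first and last theta rows
#'   represent the same physical curve (seam duplicated).
#' @return An object of class `structured_surface`.
#' @export
structured_surface <- function(x, y, z, vx = NULL, vy = NULL, vz = NULL,
                               closed_theta = FALSE) {
  stopifnot(is.matrix(x), is.matrix(y), is.matrix(z))
  d <- dim(x)
  if (!identical(d, dim(y)) || !identical(d, dim(z)))
    stop("coordinate matrices must share dimensions")
  if (any(d < 4L)) stop("structured_surface requires a grid of at least 4 x 4")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("surface positions must be finite")
  zero <- matrix(0, d[1], d[2])
  if (is.null(vx)) vx <- zero
  if (is.null(vy)) vy <- zero
  if (is.null(vz)) vz <- zero
  if (closed_theta) {
    gap <- max(abs(x[1, ] - x[d[1], ]), abs(y[1, ] - y[d[1], ]),
               abs(z[1, ] - z[d[1], ]))
    if (gap > 1e-9) stop("closed-in-theta surface must duplicate its seam row")
  }
  structure(list(x = x, y = y, z = z, vx = vx, vy = vy, vz = vz,
                 closed_theta = closed_theta),
            class = "structured_surface")
}

#' @export
print.structured_surface <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("structured_surface: %d x %d nodes (%s in theta)\n",
              d[1], d[2], if (x$closed_theta) "closed" else "open"))
  invisible(x)
}

#' @export
dim.structured_surface <- function(x) dim(x$x)

## Triangulate the quad grid: two triangles per cell, consistent orientation.
## Returns a list of 3-column index matrices (linear node indices).
surface_triangles <- function(surf) {
  d <- dim(surf$x)
  ni <- d[1]; nj <- d[2]
  i <- rep(seq_len(ni - 1L), nj - 1L)
  j <- rep(seq_len(nj - 1L), each = ni - 1L)
  n00 <- i + (j - 1L) * ni
  n10 <- n00 + 1L
  n01 <- n00 + ni
  n11 <- n01 + 1L
  rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
}

tri_coords <- function(surf, tri) {
  p <- cbind(as.vector(surf$x), as.vector(surf$y), as.vector(surf$z))
  list(a = p[tri[, 1], , drop = FALSE],
       b = p[tri[, 2], , drop = FALSE],
       c = p[tri[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Surface area by facet quadrature
#' @param surf a `structured_surface`.
#' @return total area (cm^2).
#' @export
surface_area <- function(surf) {
  tr <- tri_coords(surf, surface_triangles(surf))
  n <- cross3(tr$b - tr$a, tr$c - tr$a)
  sum(sqrt(rowSums(n^2))) / 2
}

## Facet table used by quadrature and immersed-boundary tagging:
## centroid, (non-unit) normal * 2A, area, centroid velocity.
surface_facets <- function(surf) {
  tri <- surface_triangles(surf)
  tr <- tri_coords(surf, tri)
  nvec <- cross3(tr$b - tr$a, tr$c - tr$a) / 2   # area-weighted normal
  area <- sqrt(rowSums(nvec^2))
  cen <- (tr$a + tr$b + tr$c) / 3
  v <- cbind(as.vector(surf$vx), as.vector(surf$vy), as.vector(surf$vz))
  vcen <- (v[tri[, 1], , drop = FALSE] + v[tri[, 2], , drop = FALSE] +
             v[tri[, 3], , drop = FALSE]) / 3
  list(centroid = cen, normal = nvec, area = area, velocity = vcen,
       a = tr$a, b = tr$b, c = tr$c)
}

#' Outward unit node normals
#'
#' Area-weighted average of adjacent facet normals, normalized to unit length.
#' Degenerate nodes (poles) inherit the nearest finite normal.
#' @param surf a `structured_surface`.
#' @return list of matrices `nx`, `ny`, `nz` matching the grid.
#' @export
node_normals <- function(surf) {
  d <- dim(surf$x)
  tri <- surface_triangles(surf)
  tr <- tri_coords(surf, tri)
  nvec <- cross3(tr$b - tr$a, tr$c - tr$a)
  acc <- matrix(0, prod(d), 3)
  for (k in 1:3) {
    idx <- tri[, k]
    acc[, 1] <- acc[, 1] + tabulate_sum(idx, nvec[, 1], prod(d))
    acc[, 2] <- acc[, 2] + tabulate_sum(idx, nvec[, 2], prod(d))
    acc[, 3] <- acc[, 3] + tabulate_sum(idx, nvec[, 3], prod(d))
  }
  len <- sqrt(rowSums(acc^2))
  bad <- len < 1e-12
  if (any(bad)) {
    good <- which(!bad)
    if (length(good) == 0) stop("degenerate surface: no valid normals")
    for (i in which(bad)) {
      j <- good[which.min(abs(good - i))]
      acc[i, ] <- acc[j, ]
      len[i] <- len[j]
    }
  }
  acc <- acc / len
  list(nx = matrix(acc[, 1], d[1], d[2]),
       ny = matrix(acc[, 2], d[1], d[2]),
       nz = matrix(acc[, 3], d[1], d[2]))
}

tabulate_sum <- function(idx, w, n) {
  out <- numeric(n)
  t <- tapply(w, idx, sum)
  out[as.integer(names(t))] <- t
  out
}

#' Translate a surface
#' @param surf a `structured_surface`.
#' @param offset numeric length-3 translation (cm).
#' @export
translate_surface <- function(surf, offset) {
  surf$x <- surf$x + offset[1]
  surf$y <- surf$y + offset[2]
  surf$z <- surf$z + offset[3]
  surf
}

## periodic 4th-order central derivative along rows (theta, seam excluded)
deriv_periodic <- function(m, h) {
  n <- nrow(m)
  ip1 <- c(2:n, 1); ip2 <- c(3:n, 1, 2)
  im1 <- c(n, 1:(n - 1)); im2 <- c(n - 1, n, 1:(n - 2))
  (8 * (m[ip1, , drop = FALSE] - m[im1, , drop = FALSE]) -
     (m[ip2, , drop = FALSE] - m[im2, , drop = FALSE])) / (12 * h)
}

## non-periodic derivative along columns (s): 4th-order interior,
## 2nd-order one-sided at the two edge columns
deriv_columns <- function(m, h) {
  n <- ncol(m)
  d <- matrix(0, nrow(m), n)
  if (n >= 5) {
    j <- 3:(n - 2)
    d[, j] <- (8 * (m[, j + 1] - m[, j - 1]) - (m[, j + 2] - m[, j - 2])) /
      (12 * h)
    d[, 2] <- (m[, 3] - m[, 1]) / (2 * h)
    d[, n - 1] <- (m[, n] - m[, n - 2]) / (2 * h)
  } else {
    j <- 2:(n - 1)
    d[, j] <- (m[, j + 1] - m[, j - 1]) / (2 * h)
  }
  d[, 1] <- (-3 * m[, 1] + 4 * m[, 2] - m[, 3]) / (2 * h)
  d[, n] <- (3 * m[, n] - 4 * m[, n - 1] + m[, n - 2]) / (2 * h)
  d
}

## integration weights: Simpson when the number of intervals is even,
## trapezoid otherwise
simpson_weights <- function(n, h) {
  if (n >= 3 && (n - 1) %% 2 == 0) {
    w <- rep(c(4, 2), length.out = n - 2)
    c(1, w[-length(w)], 4, 1) * h / 3
  } else {
    c(h / 2, rep(h, n - 2), h / 2)
  }
}

#' Enclosed volume of a (capped) surface by the divergence theorem
#'
#' Integrates `x . n / 3` over the parametric surface using high-order finite
#' differences of the node grid (spectral-like accuracy in the periodic theta
#' direction), plus, when needed, a planar cap closing an open boundary ring.
#' A boundary ring that collapses to a point (a pole) closes the surface by
#' itself. Boundary rings that are neither degenerate nor on the cap plane
#' raise an open-surface error.
#'
#' @param surf a `structured_surface` whose theta direction is closed.
#' @param cap_plane optional list with field `z` giving the height (cm) of a
#'   horizontal cap plane closing an open boundary ring.
#' @return enclosed volume (cm^3), positive.
#' @export
lv_volume <- function(surf, cap_plane = NULL) {
  if (!surf$closed_theta)
    stop("open surface: volume requires a theta-closed surface")
  d <- dim(surf$x)
  nt <- d[1] - 1L                       # drop duplicated seam row
  ns <- d[2]
  X <- surf$x[1:nt, , drop = FALSE]
  Y <- surf$y[1:nt, , drop = FALSE]
  Z <- surf$z[1:nt, , drop = FALSE]
  ht <- 2 * pi / nt
  hs <- 1 / (ns - 1)
  Xt <- deriv_periodic(X, ht); Yt <- deriv_periodic(Y, ht)
  Zt <- deriv_periodic(Z, ht)
  Xs <- deriv_columns(X, hs); Ys <- deriv_columns(Y, hs)
  Zs <- deriv_columns(Z, hs)
  ## integrand x . (X_theta x X_s)
  f <- X * (Yt * Zs - Zt * Ys) + Y * (Zt * Xs - Xt * Zs) +
    Z * (Xt * Ys - Yt * Xs)
  ws <- simpson_weights(ns, hs)
  vol <- abs(ht * sum(f %*% ws) / 3)    # outward-oriented surface part
  caps <- 0
  for (edge in c(1L, ns)) {
    ring <- cbind(X[, edge], Y[, edge], Z[, edge])
    ext <- max(apply(ring, 2, function(v) diff(range(v))))
    if (ext < 1e-9) next  # pole: already closed
    if (is.null(cap_plane))
      stop("open surface: boundary ring present and no cap plane given")
    if (max(abs(ring[, 3] - cap_plane$z)) > 1e-6)
      stop("open surface: boundary ring does not lie on the cap plane")
    ## planar cap at z = z0 contributes z0 * A / 3, outward normal +z when
    ## the body lies below the cap plane; shoelace area of the ring polygon
    nxt <- rbind(ring[-1, , drop = FALSE], ring[1, , drop = FALSE])
    A <- abs(sum(ring[, 1] * nxt[, 2] - nxt[, 1] * ring[, 2]) / 2)
    nz <- if (mean(Z) < cap_plane$z) 1 else -1
    caps <- caps + nz * cap_plane$z * A / 3
  }
  abs(vol + caps)
}
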