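#' Staggered Cartesian grid
#'
#' Uniform MAC grid over a rectangular box: velocity components on cell faces,
#' pressure and scalar at cell centers. Periodic in x and y; solid bottom and
#' open (zero-pressure) top along z.
#'
#' @param box list with `x`, `y`, `z`, each a length-2 numeric range (cm).
#' @param nx,ny,nz positive cell counts.
#' @return An object of class `staggered_grid`.
#' @export
build_grid <- function(box, nx, ny, nz) {
  if (nx <= 0 || ny <= 0 || nz <= 0) stop("cell counts must be positive")
  stopifnot(diff(box$x) > 0, diff(box$y) > 0, diff(box$z) > 0)
  g <- list(x0 = box$x[1], y0 = box$y[1], z0 = box$z[1],
            Lx = diff(box$x), Ly = diff(box$y), Lz = diff(box$z),
            nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz))
  g$hx <- g$Lx / nx; g$hy <- g$Ly / ny; g$hz <- g$Lz / nz
  class(g) <- "staggered_grid"
  g
}

#' @export
print.staggered_grid <- function(x, ...) {
  cat(sprintf("staggered_grid: %d x %d x %d cells, h = (%.4g, %.4g, %.4g) cm\n",
              x$nx, x$ny, x$nz, x$hx, x$hy, x$hz))
  invisible(x)
}

#' Cell-center coordinates
#' @param grid a `staggered_grid`.
#' @return list of vectors `x`, `y`, `z`.
#' @export
cell_centers <- function(grid) {
  list(x = grid$x0 + (seq_len(grid$nx) - 0.5) * grid$hx,
       y = grid$y0 + (seq_len(grid$ny) - 0.5) * grid$hy,
       z = grid$z0 + (seq_len(grid$nz) - 0.5) * grid$hz)
}

#' Face coordinate of a velocity component sample
#'
#' Round-trip accessors between face indices and physical coordinates.
#' @param grid a `staggered_grid`.
#' @param component `"u"`, `"v"` or `"w"`.
#' @param i,j,k 1-based face indices.
#' @return matrix of coordinates (one row per index triple).
#' @export
face_coord <- function(grid, component = c("u", "v", "w"), i, j, k) {
  component <- match.arg(component)
  switch(component,
    u = cbind(grid$x0 + i * grid$hx, grid$y0 + (j - 0.5) * grid$hy,
              grid$z0 + (k - 0.5) * grid$hz),
    v = cbind(grid$x0 + (i - 0.5) * grid$hx, grid$y0 + j * grid$hy,
              grid$z0 + (k - 0.5) * grid$hz),
    w = cbind(grid$x0 + (i - 0.5) * grid$hx, grid$y0 + (j - 0.5) * grid$hy,
              grid$z0 + (k - 1) * grid$hz))
}

#' Face index nearest a coordinate (inverse of [face_coord()])
#' @param grid a `staggered_grid`.
#' @param component `"u"`, `"v"` or `"w"`.
#' @param p numeric length-3 position.
#' @export
face_index <- function(grid, component = c("u", "v", "w"), p) {
  component <- match.arg(component)
  switch(component,
    u = c(round((p[1] - grid$x0) / grid$hx),
          round((p[2] - grid$y0) / grid$hy + 0.5),
          round((p[3] - grid$z0) / grid$hz + 0.5)),
    v = c(round((p[1] - grid$x0) / grid$hx + 0.5),
          round((p[2] - grid$y0) / grid$hy),
          round((p[3] - grid$z0) / grid$hz + 0.5)),
    w = c(round((p[1] - grid$x0) / grid$hx + 0.5),
          round((p[2] - grid$y0) / grid$hy + 0.5),
          round((p[3] - grid$z0) / grid$hz + 1)))
}

## empty flow-state arrays on a grid
empty_flow <- function(grid) {
  list(u = array(0, c(grid$nx, grid$ny, grid$nz)),
       v = array(0, c(grid$nx, grid$ny, grid$nz)),
       w = array(0, c(grid$nx, grid$ny, grid$nz + 1L)),
       p = array(0, c(grid$nx, grid$ny, grid$nz)),
       C = array(0, c(grid$nx, grid$ny, grid$nz)),
       t = 0)
}
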