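#' Export a structured surface as STL
#'
#' @param surf a [structured_surface()].
#' @param path output file.
#' @param binary write binary STL (default) or ASCII.
#' @export
write_stl <- function(surf, path, binary = TRUE) {
  fac <- surface_facets(surf)
  keep <- fac$area > 1e-14
  a <- fac$a[keep, , drop = FALSE]; b <- fac$b[keep, , drop = FALSE]
  cc <- fac$c[keep, , drop = FALSE]
  n <- fac$normal[keep, , drop = FALSE] / fac$area[keep]
  nf <- nrow(a)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    ## interleave: normal, v1, v2, v3, attribute count
    dat <- t(cbind(n, a, b, cc))
    for (f in seq_len(nf)) {
      writeBin(as.numeric(dat[, f]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid surface", con)
    for (f in seq_len(nf)) {
      writeLines(c(
        sprintf("  facet normal %g %g %g", n[f, 1], n[f, 2], n[f, 3]),
        "    outer loop",
        sprintf("      vertex %g %g %g", a[f, 1], a[f, 2], a[f, 3]),
        sprintf("      vertex %g %g %g", b[f, 1], b[f, 2], b[f, 3]),
        sprintf("      vertex %g %g %g", cc[f, 1], cc[f, 2], cc[f, 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid surface", con)
  }
  invisible(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl)) stop("import error: no vertices found in STL")
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  nums
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(nf) || nf <= 0) stop("import error: empty or invalid STL")
  verts <- matrix(NA_real_, 3 * nf, 3)
  for (f in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12) stop("import error: truncated STL")
    readBin(con, "integer", 1, size = 2, endian = "little")
    verts[(3 * f - 2):(3 * f), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  verts
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("import error: not a PLY file")
  nv <- NA
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("import error: PLY header not terminated")
  for (l in lines[1:hdr_end]) {
    p <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(p) >= 3 && p[1] == "element" && p[2] == "vertex")
      nv <- as.integer(p[3])
  }
  if (is.na(nv) || nv <= 0) stop("import error: no vertex element in PLY")
  body <- lines[(hdr_end + 1):(hdr_end + nv)]
  do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(p)
    as.numeric(p[1:3])))
}

#' Import a surface mesh and resample it onto a structured grid
#'
#' Reads an STL (binary or ASCII) or PLY (ASCII) mesh and resamples its
#' vertex cloud onto a structured (theta, s) grid by spherical
#' parameterization about the centroid (theta = azimuth, s = normalized
#' colatitude): the grid radius at each node is an inverse-distance-weighted
#' average of nearby vertex radii.
#'
#' @param path mesh file.
#' @param format `"STL"` or `"PLY"`; guessed from the extension by default.
#' @param n_theta,n_s resampling resolution.
#' @return a [structured_surface()] with attribute `max_deviation` (cm), the
#'   largest distance between an input vertex and its resampled radius.
#' @export
import_surface <- function(path, format = NULL, n_theta = 64L, n_s = 32L) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("import error: file missing or empty")
  if (is.null(format))
    format <- toupper(tools::file_ext(path))
  format <- match.arg(format, c("STL", "PLY"))
  verts <- if (format == "PLY") read_ply_ascii(path) else {
    head <- readBin(path, "raw", 5)
    if (rawToChar(head) == "solid") {
      v <- tryCatch(read_stl_ascii(path), error = function(e) NULL)
      if (is.null(v)) read_stl_binary(path) else v
    } else read_stl_binary(path)
  }
  if (!all(is.finite(verts))) stop("import error: non-finite vertices")
  cen <- colMeans(verts)
  rel <- sweep(verts, 2, cen)
  r <- sqrt(rowSums(rel^2))
  if (any(r < 1e-12)) stop("import error: degenerate vertex at centroid")
  th <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  psi <- acos(pmin(pmax(rel[, 3] / r, -1), 1))   # colatitude from +z
  ## grid in theta and in the colatitude band actually covered by the data
  ## (open-capped shapes do not span the full sphere)
  plo <- stats::quantile(psi, 0.001); phi_ <- stats::quantile(psi, 0.999)
  gt <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  gs <- seq(plo, phi_, length.out = n_s + 1L)
  R <- matrix(0, n_theta, n_s + 1L)
  sig_t <- 0.75 * 2 * pi / n_theta; sig_s <- 0.75 * (phi_ - plo) / n_s
  for (j in seq_len(n_s + 1L)) {
    dpsi <- psi - gs[j]
    sel <- which(abs(dpsi) < 3 * sig_s)
    if (!length(sel)) sel <- order(abs(dpsi))[1:10]
    wps <- exp(-(dpsi[sel] / sig_s)^2)
    dp <- dpsi[sel]
    for (i in seq_len(n_theta)) {
      dth <- (th[sel] - gt[i] + pi) %% (2 * pi) - pi
      wt <- wps * exp(-(dth / sig_t)^2)
      if (sum(wt) < 1e-12) {
        k <- sel[which.min(abs(dth))]
        R[i, j] <- r[k]
        next
      }
      ## weighted local-linear fit in colatitude: removes the first-order
      ## smoothing bias of a plain weighted mean at the band edges
      m0 <- sum(wt); m1 <- sum(wt * dp); m2 <- sum(wt * dp^2)
      b0 <- sum(wt * r[sel]); b1 <- sum(wt * dp * r[sel])
      den <- m0 * m2 - m1^2
      R[i, j] <- if (den > 1e-12 * m0 * max(m2, 1e-12))
        (m2 * b0 - m1 * b1) / den else b0 / m0
    }
  }
  R <- rbind(R, R[1, ])
  x <- cen[1] + outer(cos(c(gt, gt[1])), rep(1, n_s + 1L)) *
    R * matrix(rep(sin(gs), each = n_theta + 1L), n_theta + 1L)
  y <- cen[2] + outer(sin(c(gt, gt[1])), rep(1, n_s + 1L)) *
    R * matrix(rep(sin(gs), each = n_theta + 1L), n_theta + 1L)
  z <- cen[3] + R * matrix(rep(cos(gs), each = n_theta + 1L), n_theta + 1L)
  out <- structured_surface(x, y, z, closed_theta = TRUE)
  ## deviation: input vertex radii against the bilinearly interpolated
  ## gridded radius field
  ft <- th / (2 * pi) * n_theta
  i0 <- pmin(floor(ft), n_theta - 1); wtt <- ft - i0
  fs <- pmin(pmax((psi - plo) / (phi_ - plo), 0), 1) * n_s
  j0 <- pmin(floor(fs), n_s - 1); wss <- fs - j0
  Rint <- (1 - wtt) * (1 - wss) * R[cbind(i0 + 1, j0 + 1)] +
    wtt * (1 - wss) * R[cbind(i0 + 2, j0 + 1)] +
    (1 - wtt) * wss * R[cbind(i0 + 1, j0 + 2)] +
    wtt * wss * R[cbind(i0 + 2, j0 + 2)]
  attr(out, "max_deviation") <- max(abs(Rint - r))
  out
}

#' Write a structured surface as legacy VTK PolyData
#' @param surf a [structured_surface()].
#' @param path output `.vtk` file.
#' @export
write_vtk_surface <- function(surf, path) {
  d <- dim(surf$x)
  pts <- cbind(as.vector(surf$x), as.vector(surf$y), as.vector(surf$z))
  tri <- surface_triangles(surf) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "structured surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(pts))), con)
  utils::write.table(pts, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(tri), 4 * nrow(tri)), con)
  utils::write.table(cbind(3L, tri), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a flow snapshot as legacy VTK ImageData
#'
#' Cell-centered velocity (face-averaged), pressure, concentration and mask.
#' @param flow flow state.
#' @param grid a [build_grid()] grid.
#' @param tag cell classification (or `NULL`).
#' @param path output `.vtk` file.
#' @export
write_vtk_snapshot <- function(flow, grid, tag, path) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  uc <- (flow$u + flow$u[c(nx, 1:(nx - 1)), , , drop = FALSE]) / 2
  vc <- (flow$v + flow$v[, c(ny, 1:(ny - 1)), , drop = FALSE]) / 2
  wc <- (flow$w[, , 1:nz, drop = FALSE] +
           flow$w[, , 2:(nz + 1), drop = FALSE]) / 2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("flow snapshot t=%g", flow$t), "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", nx, ny, nz),
               sprintf("ORIGIN %g %g %g", grid$x0 + grid$hx / 2,
                       grid$y0 + grid$hy / 2, grid$z0 + grid$hz / 2),
               sprintf("SPACING %g %g %g", grid$hx, grid$hy, grid$hz),
               sprintf("POINT_DATA %d", nx * ny * nz),
               "VECTORS velocity float"), con)
  utils::write.table(cbind(as.vector(uc), as.vector(vc), as.vector(wc)),
                     con, row.names = FALSE, col.names = FALSE)
  writeLines(c("SCALARS pressure float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(flow$p), trim = TRUE), con)
  writeLines(c("SCALARS concentration float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(flow$C), trim = TRUE), con)
  if (!is.null(tag)) {
    writeLines(c("SCALARS mask int 1", "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(tag$mask), trim = TRUE), con)
  }
  invisible(path)
}

#' Save / load an exact-restart checkpoint
#'
#' The checkpoint holds the full flow state, valve angles and configuration;
#' restarting from it reproduces the subsequent trajectory bit-compatibly at
#' fixed dt.
#'
#' @param result a `simulation_result` or a list with `flow` and `config`.
#' @param path checkpoint file (RDS).
#' @export
save_checkpoint <- function(result, path) {
  saveRDS(list(flow = result$flow, config = result$config), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
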