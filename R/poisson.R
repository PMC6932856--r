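## cache of DFT matrices, keyed by size and direction
.dft_cache <- new.env(parent = emptyenv())
dft_matrix <- function(n, inverse = FALSE) {
  key <- paste0(n, if (inverse) "i" else "f")
  m <- .dft_cache[[key]]
  if (is.null(m)) {
    s <- if (inverse) 2i else -2i
    m <- exp(s * pi * outer(0:(n - 1), 0:(n - 1)) / n)
    .dft_cache[[key]] <- m
  }
  m
}

## 2D DFT over the first two dimensions of a 3D array (periodic x, y),
## evaluated as dense matrix products (BLAS); faster than repeated FFT calls
## at the solver's grid sizes and called every projection
fft_xy <- function(a, inverse = FALSE) {
  d <- dim(a)
  Dx <- dft_matrix(d[1], inverse)
  Dy <- dft_matrix(d[2], inverse)
  b <- Dx %*% matrix(a, d[1], d[2] * d[3])
  dim(b) <- d
  ## y transform: slice %*% t(Dy) per z-plane
  b <- matrix(aperm(array(b, d), c(2, 1, 3)), d[2], d[1] * d[3])
  b <- Dy %*% b
  aperm(array(b, c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Pressure Poisson solve on the staggered grid
#'
#' Solves the discrete `lap(phi) = rhs` with the box boundary conditions of
#' the solver: periodic in x and y (handled by FFT with modified wavenumbers),
#' homogeneous Neumann at the solid bottom face and homogeneous Dirichlet on
#' the open top face (tridiagonal solve per horizontal wavenumber).
#'
#' @param rhs cell-centered right-hand side, array `(nx, ny, nz)`.
#' @param grid a [build_grid()] grid.
#' @param zper if `TRUE`, solve with periodic conditions in z as well (used by
#'   the fully periodic verification mode); the mean mode is set to zero.
#' @return cell-centered solution array.
#' @export
solve_poisson <- function(rhs, grid, zper = FALSE) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  if (zper) {
    lam <- outer(outer((2 * cos(2 * pi * (0:(nx - 1)) / nx) - 2) / grid$hx^2,
                       (2 * cos(2 * pi * (0:(ny - 1)) / ny) - 2) / grid$hy^2,
                       `+`),
                 (2 * cos(2 * pi * (0:(nz - 1)) / nz) - 2) / grid$hz^2, `+`)
    rhat <- fft(rhs)
    lam[1, 1, 1] <- 1
    rhat[1, 1, 1] <- 0
    return(Re(fft(rhat / lam, inverse = TRUE)) / (nx * ny * nz))
  }
  array(poisson_fft_box(rhs, nx, ny, nz, grid$hx, grid$hy, grid$hz),
        c(nx, ny, nz))
}

#' Masked pressure Poisson solve over the fluid region
#'
#' Solves the fluid-only discrete Poisson problem (zero-gradient closure at
#' faces shared with immersed-boundary or exterior cells, solid bottom,
#' Dirichlet-0 above fluid top cells) by preconditioned conjugate gradients,
#' using the full-box FFT solver [solve_poisson()] as preconditioner. Because
#' the exterior is excluded, an expanding cavity can only draw fluid through
#' its orifices, never through its walls.
#'
#' @param rhs cell-centered right-hand side (zeroed in solid cells).
#' @param grid a [build_grid()] grid.
#' @param mask cell classification (0 fluid).
#' @param phi0 optional warm-start solution.
#' @param rtol relative residual tolerance (2-norm).
#' @param maxit iteration cap.
#' @return list with `phi` and the achieved relative residual `rel`.
#' @export
solve_poisson_masked <- function(rhs, grid, mask, phi0 = NULL,
                                 rtol = 1e-8, maxit = 300L) {
  g <- grid
  if (is.null(phi0)) phi0 <- numeric(0)
  sol <- masked_poisson_pcg(rhs, mask, phi0, g$nx, g$ny, g$nz,
                            g$hx, g$hy, g$hz, rtol, as.integer(maxit))
  sol$phi <- array(sol$phi, dim(rhs))
  sol
}

## apply the discrete Laplacian with the solver's boundary closures
## (used in verification tests)
laplacian_ref <- function(phi, grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  ip <- c(2:nx, 1); im <- c(nx, 1:(nx - 1))
  jp <- c(2:ny, 1); jm <- c(ny, 1:(ny - 1))
  out <- (phi[ip, , , drop = FALSE] - 2 * phi + phi[im, , , drop = FALSE]) /
    grid$hx^2 +
    (phi[, jp, , drop = FALSE] - 2 * phi + phi[, jm, , drop = FALSE]) /
    grid$hy^2
  up <- array(0, dim(phi)); dn <- array(0, dim(phi))
  up[, , 1:(nz - 1)] <- phi[, , 2:nz]
  up[, , nz] <- -phi[, , nz]           # Dirichlet ghost above top face
  dn[, , 2:nz] <- phi[, , 1:(nz - 1)]
  dn[, , 1] <- phi[, , 1]              # Neumann ghost below bottom face
  out + (up - 2 * phi + dn) / grid$hz^2
}
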