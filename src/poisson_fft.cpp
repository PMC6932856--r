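// Full-box FFT(x,y) + tridiagonal(z) pressure solve, used directly for
// body-free domains and as the preconditioner of the masked fluid solve.
// Boundary conditions: periodic x/y, Neumann bottom, Dirichlet-0 top face.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector poisson_fft_box(NumericVector rhs, int nx, int ny, int nz,
                              double hx, double hy, double hz) {
  arma::cx_cube R(nx, ny, nz);
  {
    const double *p = rhs.begin();
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          R(i, j, k) = arma::cx_double(p[i + nx * (j + ny * k)], 0.0);
  }
  // forward transforms: columns are x; rows transposed for y
  for (int k = 0; k < nz; ++k) {
    R.slice(k) = arma::fft(R.slice(k));
    R.slice(k) = arma::strans(arma::fft(arma::strans(R.slice(k))));
  }
  // modified wavenumbers
  arma::vec lamx(nx), lamy(ny);
  for (int i = 0; i < nx; ++i)
    lamx[i] = (2.0 * std::cos(2.0 * M_PI * i / nx) - 2.0) / (hx * hx);
  for (int j = 0; j < ny; ++j)
    lamy[j] = (2.0 * std::cos(2.0 * M_PI * j / ny) - 2.0) / (hy * hy);
  double ihz2 = 1.0 / (hz * hz);
  std::vector<arma::cx_double> d(nz);
  std::vector<double> cp(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double lam = lamx[i] + lamy[j];
      // Thomas algorithm in z: Neumann bottom, Dirichlet top-face ghost
      double b0 = -ihz2 + lam;
      cp[0] = ihz2 / b0;
      d[0] = R(i, j, 0) / b0;
      for (int k = 1; k < nz; ++k) {
        double bk = (k == nz - 1 ? -3.0 * ihz2 : -2.0 * ihz2) + lam;
        double m = bk - ihz2 * cp[k - 1];
        cp[k] = ihz2 / m;
        d[k] = (R(i, j, k) - ihz2 * d[k - 1]) / m;
      }
      R(i, j, nz - 1) = d[nz - 1];
      for (int k = nz - 2; k >= 0; --k)
        R(i, j, k) = d[k] - cp[k] * R(i, j, k + 1);
    }
  // inverse transforms
  for (int k = 0; k < nz; ++k) {
    R.slice(k) = arma::strans(arma::ifft(arma::strans(R.slice(k))));
    R.slice(k) = arma::ifft(R.slice(k));
  }
  NumericVector out(nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        out[i + nx * (j + ny * k)] = R(i, j, k).real();
  return out;
}

// masked-fluid PCG built on the box solve above; see solve_poisson_masked()
static void box_solve_inplace(arma::cx_cube &R, int nx, int ny, int nz,
                              double hx, double hy, double hz) {
  for (int k = 0; k < nz; ++k) {
    R.slice(k) = arma::fft(R.slice(k));
    R.slice(k) = arma::strans(arma::fft(arma::strans(R.slice(k))));
  }
  arma::vec lamx(nx), lamy(ny);
  for (int i = 0; i < nx; ++i)
    lamx[i] = (2.0 * std::cos(2.0 * M_PI * i / nx) - 2.0) / (hx * hx);
  for (int j = 0; j < ny; ++j)
    lamy[j] = (2.0 * std::cos(2.0 * M_PI * j / ny) - 2.0) / (hy * hy);
  double ihz2 = 1.0 / (hz * hz);
  std::vector<arma::cx_double> d(nz);
  std::vector<double> cp(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double lam = lamx[i] + lamy[j];
      double b0 = -ihz2 + lam;
      cp[0] = ihz2 / b0;
      d[0] = R(i, j, 0) / b0;
      for (int k = 1; k < nz; ++k) {
        double bk = (k == nz - 1 ? -3.0 * ihz2 : -2.0 * ihz2) + lam;
        double m = bk - ihz2 * cp[k - 1];
        cp[k] = ihz2 / m;
        d[k] = (R(i, j, k) - ihz2 * d[k - 1]) / m;
      }
      R(i, j, nz - 1) = d[nz - 1];
      for (int k = nz - 2; k >= 0; --k)
        R(i, j, k) = d[k] - cp[k] * R(i, j, k + 1);
    }
  for (int k = 0; k < nz; ++k) {
    R.slice(k) = arma::strans(arma::ifft(arma::strans(R.slice(k))));
    R.slice(k) = arma::ifft(R.slice(k));
  }
}

static inline int wrapp(int i, int n) { return (i % n + n) % n; }

// y = -L_masked x (SPD form; solid rows identity)
static void masked_neglap(const std::vector<double> &x, std::vector<double> &y,
                          const int *M, int nx, int ny, int nz,
                          double hx, double hy, double hz) {
  double ihx2 = 1.0 / (hx * hx), ihy2 = 1.0 / (hy * hy),
         ihz2 = 1.0 / (hz * hz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = i + nx * (j + ny * k);
        if (M[id] != 0) { y[id] = x[id]; continue; }
        double acc = 0, pc = x[id];
        int nb;
        nb = wrapp(i + 1, nx) + nx * (j + ny * k);
        if (M[nb] == 0) acc += (x[nb] - pc) * ihx2;
        nb = wrapp(i - 1, nx) + nx * (j + ny * k);
        if (M[nb] == 0) acc += (x[nb] - pc) * ihx2;
        nb = i + nx * (wrapp(j + 1, ny) + ny * k);
        if (M[nb] == 0) acc += (x[nb] - pc) * ihy2;
        nb = i + nx * (wrapp(j - 1, ny) + ny * k);
        if (M[nb] == 0) acc += (x[nb] - pc) * ihy2;
        if (k + 1 < nz) {
          nb = id + nx * ny;
          if (M[nb] == 0) acc += (x[nb] - pc) * ihz2;
        } else {
          acc += -2.0 * pc * ihz2;
        }
        if (k > 0) {
          nb = id - nx * ny;
          if (M[nb] == 0) acc += (x[nb] - pc) * ihz2;
        }
        y[id] = -acc;
      }
}

// [[Rcpp::export]]
List masked_poisson_pcg(NumericVector rhs, IntegerVector mask,
                        NumericVector phi0, int nx, int ny, int nz,
                        double hx, double hy, double hz,
                        double rtol, int maxit) {
  int N = nx * ny * nz;
  const int *M = mask.begin();
  std::vector<double> b(N), x(N), r(N), z(N), p(N), Ap(N);
  double bn2 = 0;
  for (int i = 0; i < N; ++i) {
    b[i] = (M[i] == 0) ? rhs[i] : 0.0;
    bn2 += b[i] * b[i];
    x[i] = (M[i] == 0 && phi0.size() == N) ? phi0[i] : 0.0;
  }
  double bn = std::sqrt(bn2);
  if (!std::isfinite(bn))
    stop("divergence error: non-finite field entered the pressure solve");
  NumericVector out(N);
  if (bn == 0)
    return List::create(_["phi"] = out, _["rel"] = 0.0,
                        _["iterations"] = 0);
  auto precond = [&](const std::vector<double> &rin,
                     std::vector<double> &zout) {
    arma::cx_cube R(nx, ny, nz);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          R(i, j, k) = arma::cx_double(rin[i + nx * (j + ny * k)], 0.0);
    box_solve_inplace(R, nx, ny, nz, hx, hy, hz);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int id = i + nx * (j + ny * k);
          zout[id] = (M[id] == 0) ? -R(i, j, k).real() : rin[id];
        }
  };
  masked_neglap(x, Ap, M, nx, ny, nz, hx, hy, hz);
  double rn2 = 0;
  for (int i = 0; i < N; ++i) {
    r[i] = (M[i] == 0) ? (-b[i] - Ap[i]) : 0.0;
    rn2 += r[i] * r[i];
  }
  precond(r, z);
  p = z;
  double rz = 0;
  for (int i = 0; i < N; ++i) rz += r[i] * z[i];
  double rel = std::sqrt(rn2) / bn;
  int it = 0;
  while (rel > rtol && it < maxit) {
    masked_neglap(p, Ap, M, nx, ny, nz, hx, hy, hz);
    double pAp = 0;
    for (int i = 0; i < N; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0) break;
    double alpha = rz / pAp;
    rn2 = 0;
    for (int i = 0; i < N; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rn2 += r[i] * r[i];
    }
    rel = std::sqrt(rn2) / bn;
    if (rel <= rtol) break;
    precond(r, z);
    double rz_new = 0;
    for (int i = 0; i < N; ++i) rz_new += r[i] * z[i];
    double beta = rz_new / rz;
    for (int i = 0; i < N; ++i) p[i] = z[i] + beta * p[i];
    rz = rz_new;
    ++it;
  }
  for (int i = 0; i < N; ++i) out[i] = (M[i] == 0) ? x[i] : 0.0;
  return List::create(_["phi"] = out, _["rel"] = rel,
                      _["iterations"] = it);
}
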