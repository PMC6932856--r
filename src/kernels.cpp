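// Low-level kernels for the staggered-grid immersed-boundary solver.
//
// Array conventions (column-major, R layout):
//   cell-centered fields: dims (nx, ny, nz), cell (i,j,k) center at
//     (x0+(i+.5)hx, y0+(j+.5)hy, z0+(k+.5)hz), 0-based here.
//   u: (nx, ny, nz), u(i,j,k) lives on the x-face between cells i and i+1
//     (periodic wrap), at x0+(i+1)hx.
//   v: (nx, ny, nz), y-face between j and j+1 (periodic).
//   w: (nx, ny, nz+1), z-face below cell k; w(.,.,0) is the bottom box face,
//     w(.,.,nz) the top box face.
// Boundary conditions: periodic in x and y; solid bottom (w = 0, free-slip
// tangential), open top (zero pressure; tangential zero-gradient).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline int wrapi(int i, int n) { return (i % n + n) % n; }

#define IDX(i, j, k) ((i) + nx * ((j) + ny * (k)))
#define IDW(i, j, k) ((i) + nx * ((j) + ny * (k)))  // w uses nz+1 planes

// ---------------------------------------------------------------------------
// momentum RHS: skew-symmetric advection (divergence form minus half the
// velocity times the interpolated divergence) plus viscous diffusion
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List momentum_rhs(NumericVector u, NumericVector v, NumericVector w,
                  int nx, int ny, int nz,
                  double hx, double hy, double hz, double nu,
                  int zper = 0, double art = 0.0) {
  NumericVector ru(nx * ny * nz), rv(nx * ny * nz), rw(nx * ny * (nz + 1));
  const double *U = u.begin(), *V = v.begin(), *W = w.begin();

  // cell divergence (for the skew correction)
  std::vector<double> div(nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int im = wrapi(i - 1, nx), jm = wrapi(j - 1, ny);
        div[IDX(i, j, k)] =
          (U[IDX(i, j, k)] - U[IDX(im, j, k)]) / hx +
          (V[IDX(i, j, k)] - V[IDX(i, jm, k)]) / hy +
          (W[IDW(i, j, k + 1)] - W[IDW(i, j, k)]) / hz;
      }

  // --- u component -------------------------------------------------------
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int ip = wrapi(i + 1, nx), im = wrapi(i - 1, nx);
        int jp = wrapi(j + 1, ny), jm = wrapi(j - 1, ny);
        double uc = U[IDX(i, j, k)];
        // d(uu)/dx with cell-centered averages
        double uxp = 0.5 * (U[IDX(i, j, k)] + U[IDX(ip, j, k)]); // center i+1
        double uxm = 0.5 * (U[IDX(im, j, k)] + U[IDX(i, j, k)]); // center i
        // optional local Lax-Friedrichs blend stabilizes under-resolved jets
        double adv = ((uxp * uxp -
                       art * std::fabs(uxp) * 0.5 * (U[IDX(ip, j, k)] - uc)) -
                      (uxm * uxm -
                       art * std::fabs(uxm) * 0.5 * (uc - U[IDX(im, j, k)]))) / hx;
        // d(uv)/dy at xy-corners
        double vyp = 0.5 * (V[IDX(i, j, k)] + V[IDX(ip, j, k)]);
        double vym = 0.5 * (V[IDX(i, jm, k)] + V[IDX(ip, jm, k)]);
        double uyp = 0.5 * (U[IDX(i, j, k)] + U[IDX(i, jp, k)]);
        double uym = 0.5 * (U[IDX(i, jm, k)] + U[IDX(i, j, k)]);
        adv += ((uyp * vyp -
                 art * std::fabs(vyp) * 0.5 * (U[IDX(i, jp, k)] - uc)) -
                (uym * vym -
                 art * std::fabs(vym) * 0.5 * (uc - U[IDX(i, jm, k)]))) / hy;
        // d(uw)/dz at xz-corners; wall at bottom (flux 0), zero-gradient top
        double wzp = 0.5 * (W[IDW(i, j, k + 1)] + W[IDW(ip, j, k + 1)]);
        double wzm = 0.5 * (W[IDW(i, j, k)] + W[IDW(ip, j, k)]);
        int kcp = (k == nz - 1) ? (zper ? 0 : -1) : k + 1;
        int kcm = (k == 0) ? (zper ? nz - 1 : -1) : k - 1;
        double uzp = (kcp < 0) ? uc : 0.5 * (uc + U[IDX(i, j, kcp)]);
        double uzm = (kcm < 0) ? uc : 0.5 * (U[IDX(i, j, kcm)] + uc);
        double duzp = (kcp < 0) ? 0.0 : (U[IDX(i, j, kcp)] - uc);
        double duzm = (kcm < 0) ? 0.0 : (uc - U[IDX(i, j, kcm)]);
        adv += ((uzp * wzp - art * std::fabs(wzp) * 0.5 * duzp) -
                (uzm * wzm - art * std::fabs(wzm) * 0.5 * duzm)) / hz;
        // skew correction
        double dv = 0.5 * (div[IDX(i, j, k)] + div[IDX(ip, j, k)]);
        adv -= 0.5 * uc * dv;
        // diffusion (free-slip mirror at z walls)
        double uzz_p = (kcp < 0) ? uc : U[IDX(i, j, kcp)];
        double uzz_m = (kcm < 0) ? uc : U[IDX(i, j, kcm)];
        double lap =
          (U[IDX(ip, j, k)] - 2 * uc + U[IDX(im, j, k)]) / (hx * hx) +
          (U[IDX(i, jp, k)] - 2 * uc + U[IDX(i, jm, k)]) / (hy * hy) +
          (uzz_p - 2 * uc + uzz_m) / (hz * hz);
        ru[IDX(i, j, k)] = -adv + nu * lap;
      }

  // --- v component -------------------------------------------------------
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int ip = wrapi(i + 1, nx), im = wrapi(i - 1, nx);
        int jp = wrapi(j + 1, ny), jm = wrapi(j - 1, ny);
        double vc = V[IDX(i, j, k)];
        double vyp = 0.5 * (V[IDX(i, j, k)] + V[IDX(i, jp, k)]);
        double vym = 0.5 * (V[IDX(i, jm, k)] + V[IDX(i, j, k)]);
        double adv = ((vyp * vyp -
                       art * std::fabs(vyp) * 0.5 * (V[IDX(i, jp, k)] - vc)) -
                      (vym * vym -
                       art * std::fabs(vym) * 0.5 * (vc - V[IDX(i, jm, k)]))) / hy;
        double uxp = 0.5 * (U[IDX(i, j, k)] + U[IDX(i, jp, k)]);
        double uxm = 0.5 * (U[IDX(im, j, k)] + U[IDX(im, jp, k)]);
        double vxp = 0.5 * (V[IDX(i, j, k)] + V[IDX(ip, j, k)]);
        double vxm = 0.5 * (V[IDX(im, j, k)] + V[IDX(i, j, k)]);
        adv += ((vxp * uxp - art * std::fabs(uxp) * 0.5 * (V[IDX(ip, j, k)] - vc)) -
                (vxm * uxm - art * std::fabs(uxm) * 0.5 * (vc - V[IDX(im, j, k)]))) / hx;
        double wzp = 0.5 * (W[IDW(i, j, k + 1)] + W[IDW(i, jp, k + 1)]);
        double wzm = 0.5 * (W[IDW(i, j, k)] + W[IDW(i, jp, k)]);
        int kcp = (k == nz - 1) ? (zper ? 0 : -1) : k + 1;
        int kcm = (k == 0) ? (zper ? nz - 1 : -1) : k - 1;
        double vzp = (kcp < 0) ? vc : 0.5 * (vc + V[IDX(i, j, kcp)]);
        double vzm = (kcm < 0) ? vc : 0.5 * (V[IDX(i, j, kcm)] + vc);
        double dvzp = (kcp < 0) ? 0.0 : (V[IDX(i, j, kcp)] - vc);
        double dvzm = (kcm < 0) ? 0.0 : (vc - V[IDX(i, j, kcm)]);
        adv += ((vzp * wzp - art * std::fabs(wzp) * 0.5 * dvzp) -
                (vzm * wzm - art * std::fabs(wzm) * 0.5 * dvzm)) / hz;
        double dv = 0.5 * (div[IDX(i, j, k)] + div[IDX(i, jp, k)]);
        adv -= 0.5 * vc * dv;
        double vzz_p = (kcp < 0) ? vc : V[IDX(i, j, kcp)];
        double vzz_m = (kcm < 0) ? vc : V[IDX(i, j, kcm)];
        double lap =
          (V[IDX(ip, j, k)] - 2 * vc + V[IDX(im, j, k)]) / (hx * hx) +
          (V[IDX(i, jp, k)] - 2 * vc + V[IDX(i, jm, k)]) / (hy * hy) +
          (vzz_p - 2 * vc + vzz_m) / (hz * hz);
        rv[IDX(i, j, k)] = -adv + nu * lap;
      }

  // --- w component (interior z faces only; box faces handled by BC;
  //     in fully periodic mode the k = 0 face is computed with wrap) ------
  for (int k = (zper ? 0 : 1); k < nz; ++k)   // face below cell k
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int ip = wrapi(i + 1, nx), im = wrapi(i - 1, nx);
        int jp = wrapi(j + 1, ny), jm = wrapi(j - 1, ny);
        int km = (k == 0) ? nz - 1 : k - 1;   // only reached when zper
        double wc = W[IDW(i, j, k)];
        double wzp = 0.5 * (W[IDW(i, j, k)] + W[IDW(i, j, k + 1)]); // cell k
        double wzm = 0.5 * (W[IDW(i, j, km)] + W[IDW(i, j, k)]);  // cell k-1
        double adv = ((wzp * wzp -
                       art * std::fabs(wzp) * 0.5 * (W[IDW(i, j, k + 1)] - wc)) -
                      (wzm * wzm -
                       art * std::fabs(wzm) * 0.5 * (wc - W[IDW(i, j, km)]))) / hz;
        double uxp = 0.5 * (U[IDX(i, j, k)] + U[IDX(i, j, km)]);
        double uxm = 0.5 * (U[IDX(im, j, k)] + U[IDX(im, j, km)]);
        double wxp = 0.5 * (W[IDW(i, j, k)] + W[IDW(ip, j, k)]);
        double wxm = 0.5 * (W[IDW(im, j, k)] + W[IDW(i, j, k)]);
        adv += ((wxp * uxp - art * std::fabs(uxp) * 0.5 * (W[IDW(ip, j, k)] - wc)) -
                (wxm * uxm - art * std::fabs(uxm) * 0.5 * (wc - W[IDW(im, j, k)]))) / hx;
        double vyp = 0.5 * (V[IDX(i, j, k)] + V[IDX(i, j, km)]);
        double vym = 0.5 * (V[IDX(i, jm, k)] + V[IDX(i, jm, km)]);
        double wyp = 0.5 * (W[IDW(i, j, k)] + W[IDW(i, jp, k)]);
        double wym = 0.5 * (W[IDW(i, jm, k)] + W[IDW(i, j, k)]);
        adv += ((wyp * vyp - art * std::fabs(vyp) * 0.5 * (W[IDW(i, jp, k)] - wc)) -
                (wym * vym - art * std::fabs(vym) * 0.5 * (wc - W[IDW(i, jm, k)]))) / hy;
        double dv = 0.5 * (div[IDX(i, j, km)] + div[IDX(i, j, k)]);
        adv -= 0.5 * wc * dv;
        double wzz_p = W[IDW(i, j, k + 1)];
        double wzz_m = W[IDW(i, j, km)];
        double lap =
          (W[IDW(ip, j, k)] - 2 * wc + W[IDW(im, j, k)]) / (hx * hx) +
          (W[IDW(i, jp, k)] - 2 * wc + W[IDW(i, jm, k)]) / (hy * hy) +
          (wzz_p - 2 * wc + wzz_m) / (hz * hz);
        rw[IDW(i, j, k)] = -adv + nu * lap;
      }
  return List::create(_["ru"] = ru, _["rv"] = rv, _["rw"] = rw);
}

// ---------------------------------------------------------------------------
// discrete divergence at cell centers
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector divergence(NumericVector u, NumericVector v, NumericVector w,
                         int nx, int ny, int nz,
                         double hx, double hy, double hz) {
  NumericVector d(nx * ny * nz);
  const double *U = u.begin(), *V = v.begin(), *W = w.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int im = wrapi(i - 1, nx), jm = wrapi(j - 1, ny);
        d[IDX(i, j, k)] =
          (U[IDX(i, j, k)] - U[IDX(im, j, k)]) / hx +
          (V[IDX(i, j, k)] - V[IDX(i, jm, k)]) / hy +
          (W[IDW(i, j, k + 1)] - W[IDW(i, j, k)]) / hz;
      }
  return d;
}

// ---------------------------------------------------------------------------
// velocity correction u <- u - dt grad(phi); phi has Dirichlet 0 ghost above
// the top plane and Neumann at the bottom
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List project_correct(NumericVector u, NumericVector v, NumericVector w,
                     NumericVector phi, int nx, int ny, int nz,
                     double hx, double hy, double hz, double dt,
                     int zper = 0) {
  NumericVector uo = clone(u), vo = clone(v), wo = clone(w);
  const double *P = phi.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int ip = wrapi(i + 1, nx), jp = wrapi(j + 1, ny);
        uo[IDX(i, j, k)] -= dt * (P[IDX(ip, j, k)] - P[IDX(i, j, k)]) / hx;
        vo[IDX(i, j, k)] -= dt * (P[IDX(i, jp, k)] - P[IDX(i, j, k)]) / hy;
        if (k > 0)
          wo[IDW(i, j, k)] -= dt * (P[IDX(i, j, k)] - P[IDX(i, j, k - 1)]) / hz;
        else if (zper)
          wo[IDW(i, j, 0)] -=
            dt * (P[IDX(i, j, 0)] - P[IDX(i, j, nz - 1)]) / hz;
      }
  if (zper) {
    // duplicated top plane mirrors the wrapped bottom face
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        wo[IDW(i, j, nz)] = wo[IDW(i, j, 0)];
  } else {
    // top face: ghost phi = -phi(nz-1) (Dirichlet 0 on the face)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        wo[IDW(i, j, nz)] -= dt * (-2.0 * P[IDX(i, j, nz - 1)]) / hz;
  }
  return List::create(_["u"] = uo, _["v"] = vo, _["w"] = wo);
}

// ---------------------------------------------------------------------------
// batched tridiagonal solve in z for the pressure Poisson equation:
// (phi[k-1] - 2 phi[k] + phi[k+1])/hz^2 + lam(col) phi[k] = rhs
// bottom: Neumann (ghost = phi[0]); top: Dirichlet on the face (ghost =
// -phi[nz-1]). rhs given as (ncol x nz) matrices (real and imaginary parts).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List tridiag_poisson(NumericMatrix rr, NumericMatrix ri, NumericVector lam,
                     double hz) {
  int ncol = rr.nrow(), nz = rr.ncol();
  NumericMatrix xr(ncol, nz), xi(ncol, nz);
  double ihz2 = 1.0 / (hz * hz);
  std::vector<double> cp(nz), dr(nz), di(nz);
  for (int c = 0; c < ncol; ++c) {
    // Thomas algorithm; diagonal: -2/hz^2 + lam (+1/hz^2 bottom Neumann,
    // -1/hz^2 extra at top from the Dirichlet ghost)
    double b0 = -1.0 * ihz2 + lam[c];
    cp[0] = ihz2 / b0;
    dr[0] = rr(c, 0) / b0;
    di[0] = ri(c, 0) / b0;
    for (int k = 1; k < nz; ++k) {
      double bk = (k == nz - 1 ? -3.0 * ihz2 : -2.0 * ihz2) + lam[c];
      double m = bk - ihz2 * cp[k - 1];
      cp[k] = ihz2 / m;
      dr[k] = (rr(c, k) - ihz2 * dr[k - 1]) / m;
      di[k] = (ri(c, k) - ihz2 * di[k - 1]) / m;
    }
    xr(c, nz - 1) = dr[nz - 1];
    xi(c, nz - 1) = di[nz - 1];
    for (int k = nz - 2; k >= 0; --k) {
      xr(c, k) = dr[k] - cp[k] * xr(c, k + 1);
      xi(c, k) = di[k] - cp[k] * xi(c, k + 1);
    }
  }
  return List::create(_["re"] = xr, _["im"] = xi);
}

// ---------------------------------------------------------------------------
// immersed-boundary tagging: rasterize triangle facets into the cell grid,
// honoring a per-surface priority; writes mask (1 = boundary), priority and
// boundary velocity in place
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
void mark_facets(IntegerVector mask, IntegerVector prio,
                 NumericVector bu, NumericVector bv, NumericVector bw,
                 NumericMatrix pa, NumericMatrix pb, NumericMatrix pc,
                 NumericMatrix vel, int priority,
                 int nx, int ny, int nz,
                 double x0, double y0, double z0,
                 double hx, double hy, double hz) {
  int nf = pa.nrow();
  double hmin = std::min(hx, std::min(hy, hz));
  for (int f = 0; f < nf; ++f) {
    double ax = pa(f, 0), ay = pa(f, 1), az = pa(f, 2);
    double bx = pb(f, 0), by = pb(f, 1), bz = pb(f, 2);
    double cx = pc(f, 0), cy = pc(f, 1), cz = pc(f, 2);
    double e1 = std::sqrt((bx - ax) * (bx - ax) + (by - ay) * (by - ay) +
                          (bz - az) * (bz - az));
    double e2 = std::sqrt((cx - ax) * (cx - ax) + (cy - ay) * (cy - ay) +
                          (cz - az) * (cz - az));
    double e3 = std::sqrt((cx - bx) * (cx - bx) + (cy - by) * (cy - by) +
                          (cz - bz) * (cz - bz));
    double emax = std::max(e1, std::max(e2, e3));
    int nsub = (int)std::ceil(emax / (0.45 * hmin)) + 1;
    if (nsub > 64) nsub = 64;
    for (int p = 0; p <= nsub; ++p)
      for (int q = 0; q <= nsub - p; ++q) {
        double al = (double)p / nsub, be = (double)q / nsub;
        double px = ax + al * (bx - ax) + be * (cx - ax);
        double py = ay + al * (by - ay) + be * (cy - ay);
        double pz = az + al * (bz - az) + be * (cz - az);
        int i = (int)std::floor((px - x0) / hx);
        int j = (int)std::floor((py - y0) / hy);
        int k = (int)std::floor((pz - z0) / hz);
        if (k < 0 || k >= nz) continue;
        i = wrapi(i, nx); j = wrapi(j, ny);
        int id = IDX(i, j, k);
        if (priority > prio[id]) {
          prio[id] = priority;
          mask[id] = 1;
          bu[id] = vel(f, 0);
          bv[id] = vel(f, 1);
          bw[id] = vel(f, 2);
        }
      }
  }
}

// ---------------------------------------------------------------------------
// exterior flood fill from seed cells through non-boundary cells (6-connected,
// periodic in x and y); mask: 1 = boundary (walls), on return 2 = exterior
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
void flood_exterior(IntegerVector mask, IntegerVector seeds,
                    int nx, int ny, int nz) {
  std::queue<int> q;
  for (int s = 0; s < seeds.size(); ++s) {
    int id = seeds[s];
    if (mask[id] == 0) { mask[id] = 2; q.push(id); }
  }
  while (!q.empty()) {
    int id = q.front(); q.pop();
    int k = id / (nx * ny), rem = id % (nx * ny);
    int j = rem / nx, i = rem % nx;
    int nb[6];
    nb[0] = IDX(wrapi(i + 1, nx), j, k);
    nb[1] = IDX(wrapi(i - 1, nx), j, k);
    nb[2] = IDX(i, wrapi(j + 1, ny), k);
    nb[3] = IDX(i, wrapi(j - 1, ny), k);
    nb[4] = (k + 1 < nz) ? IDX(i, j, k + 1) : -1;
    nb[5] = (k - 1 >= 0) ? IDX(i, j, k - 1) : -1;
    for (int t = 0; t < 6; ++t)
      if (nb[t] >= 0 && mask[nb[t]] == 0) { mask[nb[t]] = 2; q.push(nb[t]); }
  }
}

// ---------------------------------------------------------------------------
// impose boundary velocities on faces adjacent to non-fluid cells
// (mask: 0 fluid, 1 boundary, 2 exterior; exterior contributes zero velocity)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List apply_face_bc(NumericVector u, NumericVector v, NumericVector w,
                   IntegerVector mask,
                   NumericVector bu, NumericVector bv, NumericVector bw,
                   int nx, int ny, int nz) {
  NumericVector uo = clone(u), vo = clone(v), wo = clone(w);
  const int *M = mask.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = IDX(i, j, k);
        int ip = IDX(wrapi(i + 1, nx), j, k);
        int jp = IDX(i, wrapi(j + 1, ny), k);
        int m0 = M[id], m1 = M[ip], m2 = M[jp];
        if (m0 || m1) {
          double s = 0; int n = 0;
          if (m0 == 1) { s += bu[id]; ++n; }
          if (m1 == 1) { s += bu[ip]; ++n; }
          if (m0 == 2 || m1 == 2) { ++n; }   // exterior: zero contribution
          uo[id] = n ? s / n : 0.0;
        }
        if (m0 || m2) {
          double s = 0; int n = 0;
          if (m0 == 1) { s += bv[id]; ++n; }
          if (m2 == 1) { s += bv[jp]; ++n; }
          if (m0 == 2 || m2 == 2) { ++n; }
          vo[id] = n ? s / n : 0.0;
        }
        if (k > 0) {
          int km = IDX(i, j, k - 1);
          int mk = M[km];
          if (m0 || mk) {
            double s = 0; int n = 0;
            if (m0 == 1) { s += bw[id]; ++n; }
            if (mk == 1) { s += bw[km]; ++n; }
            if (m0 == 2 || mk == 2) { ++n; }
            wo[IDW(i, j, k)] = n ? s / n : 0.0;
          }
        }
      }
  // bottom box face is a wall
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      wo[IDW(i, j, 0)] = 0.0;
  return List::create(_["u"] = uo, _["v"] = vo, _["w"] = wo);
}

// ---------------------------------------------------------------------------
// scalar advection-diffusion RHS: MUSCL (minmod-limited) upwind fluxes with
// face velocities, explicit diffusion; C = 0 ghost above the top plane
// (fresh inflow), zero flux through the bottom wall; periodic x, y
// ---------------------------------------------------------------------------
static inline double minmod(double a, double b) {
  if (a * b <= 0) return 0.0;
  return (std::fabs(a) < std::fabs(b)) ? a : b;
}

// [[Rcpp::export]]
NumericVector scalar_rhs(NumericVector Cf, NumericVector u, NumericVector v,
                         NumericVector w, IntegerVector mask,
                         int nx, int ny, int nz,
                         double hx, double hy, double hz, double kappa,
                         int zper = 0) {
  NumericVector r(nx * ny * nz);
  const double *C = Cf.begin(), *U = u.begin(), *V = v.begin(),
               *W = w.begin();
  const int *M = mask.begin();
  auto cval = [&](int i, int j, int k) -> double {
    if (zper) k = wrapi(k, nz);
    else {
      if (k < 0) k = 0;               // bottom: zero-gradient
      if (k >= nz) return 0.0;        // top: fresh (C = 0)
    }
    return C[IDX(wrapi(i, nx), wrapi(j, ny), k)];
  };
  auto face_val_x = [&](int i, int j, int k, double uf) -> double {
    if (uf >= 0) {
      double c0 = cval(i, j, k);
      return c0 + 0.5 * minmod(c0 - cval(i - 1, j, k), cval(i + 1, j, k) - c0);
    }
    double c1 = cval(i + 1, j, k);
    return c1 - 0.5 * minmod(c1 - cval(i, j, k), cval(i + 2, j, k) - c1);
  };
  auto face_val_y = [&](int i, int j, int k, double vf) -> double {
    if (vf >= 0) {
      double c0 = cval(i, j, k);
      return c0 + 0.5 * minmod(c0 - cval(i, j - 1, k), cval(i, j + 1, k) - c0);
    }
    double c1 = cval(i, j + 1, k);
    return c1 - 0.5 * minmod(c1 - cval(i, j, k), cval(i, j + 2, k) - c1);
  };
  auto face_val_z = [&](int i, int j, int k, double wf) -> double {
    // face below cell k (z-face index k)
    if (wf >= 0) {
      double c0 = cval(i, j, k - 1);
      return c0 + 0.5 * minmod(c0 - cval(i, j, k - 2), cval(i, j, k) - c0);
    }
    double c1 = cval(i, j, k);
    return c1 - 0.5 * minmod(c1 - cval(i, j, k - 1), cval(i, j, k + 1) - c1);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = IDX(i, j, k);
        if (M[id] != 0) { r[id] = 0.0; continue; }
        int im = wrapi(i - 1, nx), jm = wrapi(j - 1, ny);
        double fxp = U[IDX(i, j, k)] * face_val_x(i, j, k, U[IDX(i, j, k)]);
        double fxm = U[IDX(im, j, k)] * face_val_x(i - 1, j, k, U[IDX(im, j, k)]);
        double fyp = V[IDX(i, j, k)] * face_val_y(i, j, k, V[IDX(i, j, k)]);
        double fym = V[IDX(i, jm, k)] * face_val_y(i, j - 1, k, V[IDX(i, jm, k)]);
        double wtop = W[IDW(i, j, k + 1)], wbot = W[IDW(i, j, k)];
        double fzp = wtop * face_val_z(i, j, k + 1, wtop);
        double fzm = (k == 0 && !zper) ? 0.0 : wbot * face_val_z(i, j, k, wbot);
        double adv = (fxp - fxm) / hx + (fyp - fym) / hy + (fzp - fzm) / hz;
        // diffusion: zero flux into non-fluid cells and through the bottom
        double c0 = C[id];
        double dif = 0.0;
        int ipn = IDX(wrapi(i + 1, nx), j, k), imn = IDX(im, j, k);
        if (M[ipn] == 0) dif += (C[ipn] - c0) / (hx * hx);
        if (M[imn] == 0) dif += (C[imn] - c0) / (hx * hx);
        int jpn = IDX(i, wrapi(j + 1, ny), k), jmn = IDX(i, jm, k);
        if (M[jpn] == 0) dif += (C[jpn] - c0) / (hy * hy);
        if (M[jmn] == 0) dif += (C[jmn] - c0) / (hy * hy);
        if (k < nz - 1 || zper) {
          int kpn = IDX(i, j, (k + 1) % nz);
          if (M[kpn] == 0) dif += (C[kpn] - c0) / (hz * hz);
        } else {
          dif += (0.0 - c0) / (hz * hz);   // fresh fluid above the top plane
        }
        if (k > 0 || zper) {
          int kmn = IDX(i, j, (k - 1 + nz) % nz);
          if (M[kmn] == 0) dif += (C[kmn] - c0) / (hz * hz);
        }
        r[id] = -adv + kappa * dif;
      }
  return r;
}

// ---------------------------------------------------------------------------
// trilinear interpolation of the staggered velocity at arbitrary points
// (periodic wrap in x, y; clamped in z)
// ---------------------------------------------------------------------------
static double interp_component(const double *F, double px, double py,
                               double pz, int nx, int ny, int nzp,
                               double ox, double oy, double oz,
                               double x0, double y0, double z0,
                               double hx, double hy, double hz) {
  // ox, oy, oz: offsets of the component's sample locations
  double gx = (px - x0 - ox) / hx;
  double gy = (py - y0 - oy) / hy;
  double gz = (pz - z0 - oz) / hz;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
      k0 = (int)std::floor(gz);
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  if (k0 < 0) { k0 = 0; fz = 0; }
  if (k0 > nzp - 2) { k0 = nzp - 2; fz = 1; }
  double acc = 0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        int i = wrapi(i0 + di, nx), j = wrapi(j0 + dj, ny);
        int k = k0 + dk;
        double wgt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
        acc += wgt * F[i + nx * (j + ny * k)];
      }
  return acc;
}

// [[Rcpp::export]]
NumericMatrix interp_velocity(NumericMatrix pts, NumericVector u,
                              NumericVector v, NumericVector w,
                              int nx, int ny, int nz,
                              double x0, double y0, double z0,
                              double hx, double hy, double hz) {
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int p = 0; p < n; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    // u at (x0+(i+1)hx, yc, zc) -> offset (hx, hy/2, hz/2)
    out(p, 0) = interp_component(u.begin(), px, py, pz, nx, ny, nz,
                                 hx, 0.5 * hy, 0.5 * hz, x0, y0, z0,
                                 hx, hy, hz);
    out(p, 1) = interp_component(v.begin(), px, py, pz, nx, ny, nz,
                                 0.5 * hx, hy, 0.5 * hz, x0, y0, z0,
                                 hx, hy, hz);
    out(p, 2) = interp_component(w.begin(), px, py, pz, nx, ny, nz + 1,
                                 0.5 * hx, 0.5 * hy, 0.0, x0, y0, z0,
                                 hx, hy, hz);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector interp_scalar(NumericMatrix pts, NumericVector Cf,
                            int nx, int ny, int nz,
                            double x0, double y0, double z0,
                            double hx, double hy, double hz) {
  int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p)
    out[p] = interp_component(Cf.begin(), pts(p, 0), pts(p, 1), pts(p, 2),
                              nx, ny, nz, 0.5 * hx, 0.5 * hy, 0.5 * hz,
                              x0, y0, z0, hx, hy, hz);
  return out;
}

// ---------------------------------------------------------------------------
// extend the scalar into boundary cells (mean of fluid neighbors) so that
// advective donor values at cut cells track the adjacent fluid
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector extend_scalar(NumericVector Cf, IntegerVector mask,
                            int nx, int ny, int nz) {
  NumericVector out = clone(Cf);
  const int *M = mask.begin();
  const double *C = Cf.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = IDX(i, j, k);
        if (M[id] != 1) { if (M[id] == 2) out[id] = 0.0; continue; }
        double s = 0; int n = 0;
        int nb[6] = { IDX(wrapi(i + 1, nx), j, k), IDX(wrapi(i - 1, nx), j, k),
                      IDX(i, wrapi(j + 1, ny), k), IDX(i, wrapi(j - 1, ny), k),
                      (k + 1 < nz) ? IDX(i, j, k + 1) : -1,
                      (k > 0) ? IDX(i, j, k - 1) : -1 };
        for (int t = 0; t < 6; ++t)
          if (nb[t] >= 0 && M[nb[t]] == 0) { s += C[nb[t]]; ++n; }
        if (n) out[id] = s / n;
      }
  return out;
}

// [[Rcpp::export]]
double max_cfl_rate(NumericVector u, NumericVector v, NumericVector w,
                    int nx, int ny, int nz,
                    double hx, double hy, double hz) {
  double m = 0;
  const double *U = u.begin(), *V = v.begin(), *W = w.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double r = std::fabs(U[IDX(i, j, k)]) / hx +
                   std::fabs(V[IDX(i, j, k)]) / hy +
                   std::fabs(W[IDW(i, j, k)]) / hz;
        if (r > m) m = r;
      }
  return m;
}

// ---------------------------------------------------------------------------
// masked Laplacian for the fluid-only pressure solve: fluid rows get the
// 7-point Laplacian with zero-gradient closure at faces shared with solid
// (boundary or exterior) cells and at the bottom wall, Dirichlet-0 on the
// open top face; solid rows act as -identity (decoupled)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector masked_laplacian(NumericVector phi, IntegerVector mask,
                               int nx, int ny, int nz,
                               double hx, double hy, double hz) {
  NumericVector out(nx * ny * nz);
  const double *P = phi.begin();
  const int *M = mask.begin();
  double ihx2 = 1.0 / (hx * hx), ihy2 = 1.0 / (hy * hy),
         ihz2 = 1.0 / (hz * hz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = IDX(i, j, k);
        if (M[id] != 0) { out[id] = -P[id]; continue; }
        double acc = 0, pc = P[id];
        int nb;
        nb = IDX(wrapi(i + 1, nx), j, k);
        if (M[nb] == 0) acc += (P[nb] - pc) * ihx2;
        nb = IDX(wrapi(i - 1, nx), j, k);
        if (M[nb] == 0) acc += (P[nb] - pc) * ihx2;
        nb = IDX(i, wrapi(j + 1, ny), k);
        if (M[nb] == 0) acc += (P[nb] - pc) * ihy2;
        nb = IDX(i, wrapi(j - 1, ny), k);
        if (M[nb] == 0) acc += (P[nb] - pc) * ihy2;
        if (k + 1 < nz) {
          nb = IDX(i, j, k + 1);
          if (M[nb] == 0) acc += (P[nb] - pc) * ihz2;
        } else {
          acc += (-pc - pc) * ihz2;   // open top: Dirichlet 0 on the face
        }
        if (k > 0) {
          nb = IDX(i, j, k - 1);
          if (M[nb] == 0) acc += (P[nb] - pc) * ihz2;
        }
        out[id] = acc;
      }
  return out;
}

// ---------------------------------------------------------------------------
// velocity correction restricted to open faces (both cells fluid; top face
// open only above a fluid cell); forced faces keep their boundary velocity
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List project_correct_masked(NumericVector u, NumericVector v, NumericVector w,
                            NumericVector phi, IntegerVector mask,
                            int nx, int ny, int nz,
                            double hx, double hy, double hz, double dt) {
  NumericVector uo = clone(u), vo = clone(v), wo = clone(w);
  const double *P = phi.begin();
  const int *M = mask.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = IDX(i, j, k);
        int ip = IDX(wrapi(i + 1, nx), j, k);
        int jp = IDX(i, wrapi(j + 1, ny), k);
        if (M[id] == 0 && M[ip] == 0)
          uo[id] -= dt * (P[ip] - P[id]) / hx;
        if (M[id] == 0 && M[jp] == 0)
          vo[id] -= dt * (P[jp] - P[id]) / hy;
        if (k > 0) {
          int km = IDX(i, j, k - 1);
          if (M[id] == 0 && M[km] == 0)
            wo[IDW(i, j, k)] -= dt * (P[id] - P[km]) / hz;
        }
      }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (M[IDX(i, j, nz - 1)] == 0)
        wo[IDW(i, j, nz)] -= dt * (-2.0 * P[IDX(i, j, nz - 1)]) / hz;
  return List::create(_["u"] = uo, _["v"] = vo, _["w"] = wo);
}

// ---------------------------------------------------------------------------
// connected-component labels of the fluid region (6-connected, periodic in
// x and y); non-fluid cells get 0, fluid components 1..K
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector label_fluid_components(IntegerVector mask,
                                     int nx, int ny, int nz) {
  IntegerVector lab(nx * ny * nz);
  const int *M = mask.begin();
  int next = 0;
  std::queue<int> q;
  for (int s = 0; s < nx * ny * nz; ++s) {
    if (M[s] != 0 || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      int id = q.front(); q.pop();
      int k = id / (nx * ny), rem = id % (nx * ny);
      int j = rem / nx, i = rem % nx;
      int nb[6];
      nb[0] = IDX(wrapi(i + 1, nx), j, k);
      nb[1] = IDX(wrapi(i - 1, nx), j, k);
      nb[2] = IDX(i, wrapi(j + 1, ny), k);
      nb[3] = IDX(i, wrapi(j - 1, ny), k);
      nb[4] = (k + 1 < nz) ? IDX(i, j, k + 1) : -1;
      nb[5] = (k - 1 >= 0) ? IDX(i, j, k - 1) : -1;
      for (int t = 0; t < 6; ++t)
        if (nb[t] >= 0 && M[nb[t]] == 0 && lab[nb[t]] == 0) {
          lab[nb[t]] = next;
          q.push(nb[t]);
        }
    }
  }
  return lab;
}
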