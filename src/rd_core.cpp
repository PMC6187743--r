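#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Index helper: x fastest, then y, then z (R array layout).
static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Mirror (zero-flux) or wrap (periodic) an out-of-range coordinate.
static inline int reflect(int i, int n, bool periodic) {
  if (i < 0)  return periodic ? n - 1 : 0;
  if (i >= n) return periodic ? 0 : n - 1;
  return i;
}

// 7-point Laplacian of a single field at voxel (i,j,k), spacing h.
// Zero-flux boundaries use the mirror ghost (ghost value = boundary value).
static inline double lap_at(const double *f, int i, int j, int k,
                            int nx, int ny, int nz, double inv_h2,
                            bool periodic) {
  // accumulate neighbour differences so a constant field gives exactly zero
  const double c = f[idx3(i, j, k, nx, ny)];
  double s = 0.0;
  s += f[idx3(reflect(i - 1, nx, periodic), j, k, nx, ny)] - c;
  s += f[idx3(reflect(i + 1, nx, periodic), j, k, nx, ny)] - c;
  s += f[idx3(i, reflect(j - 1, ny, periodic), k, nx, ny)] - c;
  s += f[idx3(i, reflect(j + 1, ny, periodic), k, nx, ny)] - c;
  s += f[idx3(i, j, reflect(k - 1, nz, periodic), nx, ny)] - c;
  s += f[idx3(i, j, reflect(k + 1, nz, periodic), nx, ny)] - c;
  return s * inv_h2;
}

// [[Rcpp::export]]
NumericVector laplacian_cpp(NumericVector field, IntegerVector dim,
                            double h, bool periodic) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((int)field.size() != nx * ny * nz)
    stop("field length does not match grid dimensions");
  NumericVector out(field.size());
  const double inv_h2 = 1.0 / (h * h);
  const double *f = REAL(field);
  double *o = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        o[idx3(i, j, k, nx, ny)] = lap_at(f, i, j, k, nx, ny, nz, inv_h2, periodic);
  out.attr("dim") = dim;
  return out;
}

// Advance the four-field system n_steps explicit-Euler updates.
// A, H, S diffuse; Y is purely local. Returns final fields, snapshots at the
// requested cadence, per-snapshot min/max, and the H-floor clamp count.
// [[Rcpp::export]]
List rd_run_cpp(NumericVector A0, NumericVector H0, NumericVector S0,
                NumericVector Y0, IntegerVector dim, double h, bool periodic,
                List par, double dt, int n_steps, int snapshot_every,
                double H_floor) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if ((int)A0.size() != n || (int)H0.size() != n || (int)S0.size() != n ||
      (int)Y0.size() != n)
    stop("field length does not match grid dimensions");

  const double c     = as<double>(par["c"]);
  const double mu    = as<double>(par["mu"]);
  const double nu    = as<double>(par["nu"]);
  const double rho_A = as<double>(par["rho_A"]);
  const double rho_H = as<double>(par["rho_H"]);
  const double c0    = as<double>(par["c0"]);
  const double gam   = as<double>(par["gamma"]);
  const double eps   = as<double>(par["epsilon"]);
  const double d     = as<double>(par["d"]);
  const double e     = as<double>(par["e"]);
  const double f     = as<double>(par["f"]);
  const double D_A   = as<double>(par["D_A"]);
  const double D_H   = as<double>(par["D_H"]);
  const double D_S   = as<double>(par["D_S"]);

  std::vector<double> A(A0.begin(), A0.end()), H(H0.begin(), H0.end()),
      S(S0.begin(), S0.end()), Y(Y0.begin(), Y0.end());
  std::vector<double> An(n), Hn(n), Sn(n);

  const double inv_h2 = 1.0 / (h * h);
  long clamp_count = 0;

  List snapshots;
  std::vector<int> snap_steps;
  std::vector<double> snap_stats;  // per snapshot: min/max of A,H,S,Y (8 values)

  auto take_snapshot = [&](int step) {
    NumericVector sA(A.begin(), A.end()), sH(H.begin(), H.end()),
        sS(S.begin(), S.end()), sY(Y.begin(), Y.end());
    sA.attr("dim") = dim; sH.attr("dim") = dim;
    sS.attr("dim") = dim; sY.attr("dim") = dim;
    snapshots.push_back(List::create(_["step"] = step, _["A"] = sA,
                                     _["H"] = sH, _["S"] = sS, _["Y"] = sY));
    snap_steps.push_back(step);
    const std::vector<double> *fs[4] = {&A, &H, &S, &Y};
    for (int q = 0; q < 4; ++q) {
      double lo = (*fs[q])[0], hi = (*fs[q])[0];
      for (int i = 1; i < n; ++i) {
        const double v = (*fs[q])[i];
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      snap_stats.push_back(lo);
      snap_stats.push_back(hi);
    }
  };

  for (int step = 1; step <= n_steps; ++step) {
    int bad_voxel = -1;
    const char *bad_field = "";
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int p = idx3(i, j, k, nx, ny);
          const double a = A[p], hh = H[p], s = S[p], y = Y[p];
          double hden = hh;
          if (hden < H_floor) { hden = H_floor; ++clamp_count; }
          const double auto_t = c * a * a * s;
          const double dA = auto_t / hden - mu * a + rho_A * y;
          const double dH = auto_t - nu * hh + rho_H * y;
          const double dS = c0 - gam * s - eps * y * s;
          const double dY = d * a - e * y + y * y / (1.0 + f * y * y);
          An[p] = a + dt * (dA + D_A * lap_at(A.data(), i, j, k, nx, ny, nz, inv_h2, periodic));
          Hn[p] = hh + dt * (dH + D_H * lap_at(H.data(), i, j, k, nx, ny, nz, inv_h2, periodic));
          Sn[p] = s + dt * (dS + D_S * lap_at(S.data(), i, j, k, nx, ny, nz, inv_h2, periodic));
          Y[p]  = y + dt * dY;
          if (bad_voxel < 0 &&
              !(std::isfinite(An[p]) && std::isfinite(Hn[p]) &&
                std::isfinite(Sn[p]) && std::isfinite(Y[p]))) {
            bad_voxel = p;
            bad_field = !std::isfinite(An[p]) ? "A"
                        : !std::isfinite(Hn[p]) ? "H"
                        : !std::isfinite(Sn[p]) ? "S" : "Y";
          }
        }
      }
    }
    A.swap(An); H.swap(Hn); S.swap(Sn);

    if (bad_voxel >= 0) {
      stop("non-finite value in field %s at step %d, voxel linear index %d "
           "(dt too large for these diffusion coefficients?)",
           bad_field, step, bad_voxel + 1);
    }

    if (snapshot_every > 0 && step % snapshot_every == 0) take_snapshot(step);
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector fA(A.begin(), A.end()), fH(H.begin(), H.end()),
      fS(S.begin(), S.end()), fY(Y.begin(), Y.end());
  fA.attr("dim") = dim; fH.attr("dim") = dim;
  fS.attr("dim") = dim; fY.attr("dim") = dim;

  NumericMatrix stats(snap_steps.size(), 8);
  for (size_t r = 0; r < snap_steps.size(); ++r)
    for (int q = 0; q < 8; ++q) stats(r, q) = snap_stats[r * 8 + q];

  return List::create(_["A"] = fA, _["H"] = fH, _["S"] = fS, _["Y"] = fY,
                      _["n_steps"] = n_steps,
                      _["clamp_count"] = (double)clamp_count,
                      _["snapshots"] = snapshots,
                      _["snapshot_steps"] = IntegerVector(snap_steps.begin(), snap_steps.end()),
                      _["snapshot_stats"] = stats);
}
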