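#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

// 3D binary-image utilities: 26-connected component labeling and
// topology-preserving curve thinning by sequential simple-point removal
// (Bertrand-Malandain simple-point characterization, 6 directional
// subiterations, endpoint preservation).

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if ((int)mask.size() != n) stop("mask length does not match grid dimensions");
  IntegerVector labels(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int p0 = 0; p0 < n; ++p0) {
    if (!mask[p0] || labels[p0] != 0) continue;
    ++next;
    stack.push_back(p0);
    labels[p0] = next;
    while (!stack.empty()) {
      const int p = stack.back();
      stack.pop_back();
      const int i = p % nx, j = (p / nx) % ny, k = p / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            const int q = idx3(ii, jj, kk, nx, ny);
            if (mask[q] && labels[q] == 0) {
              labels[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  labels.attr("dim") = dim;
  labels.attr("n_components") = next;
  return labels;
}

// ---- simple-point machinery on the 3x3x3 neighborhood -----------------

// offsets indexed 0..26, center = 13; off[o] = (dx,dy,dz) with dx fastest
static inline void off_decode(int o, int &dx, int &dy, int &dz) {
  dx = o % 3 - 1;
  dy = (o / 3) % 3 - 1;
  dz = o / 9 - 1;
}

// Fill nb[27] with foreground flags of the neighborhood of p (out of domain
// = background).
static void fill_nb(const std::vector<char> &m, int i, int j, int k,
                    int nx, int ny, int nz, bool nb[27]) {
  for (int o = 0; o < 27; ++o) {
    int dx, dy, dz;
    off_decode(o, dx, dy, dz);
    const int ii = i + dx, jj = j + dy, kk = k + dz;
    nb[o] = !(ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) &&
            m[idx3(ii, jj, kk, nx, ny)];
  }
}

static inline int n26_count(const bool nb[27]) {
  int c = 0;
  for (int o = 0; o < 27; ++o)
    if (o != 13 && nb[o]) ++c;
  return c;
}

// Number of 26-connected components of foreground within N26(p) \ {p}.
static int fg26_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> st{s};
    seen[s] = true;
    while (!st.empty()) {
      const int o = st.back();
      st.pop_back();
      int ax, ay, az;
      off_decode(o, ax, ay, az);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || !nb[t] || seen[t]) continue;
        int bx, by, bz;
        off_decode(t, bx, by, bz);
        if (std::abs(ax - bx) <= 1 && std::abs(ay - by) <= 1 &&
            std::abs(az - bz) <= 1) {
          seen[t] = true;
          st.push_back(t);
        }
      }
    }
  }
  return comps;
}

// Number of 6-connected components of background within N18(p) that are
// 6-adjacent to p (i.e. contain a face neighbor).
static int bg6_components(const bool nb[27]) {
  bool in18[27], seen[27] = {false};
  for (int o = 0; o < 27; ++o) {
    int dx, dy, dz;
    off_decode(o, dx, dy, dz);
    const int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
    in18[o] = (o != 13) && s <= 2;
  }
  int comps = 0;
  for (int s0 = 0; s0 < 27; ++s0) {
    int dx, dy, dz;
    off_decode(s0, dx, dy, dz);
    // seed only from background face neighbors
    if (!in18[s0] || nb[s0] || seen[s0]) continue;
    if (std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
    ++comps;
    std::vector<int> st{s0};
    seen[s0] = true;
    while (!st.empty()) {
      const int o = st.back();
      st.pop_back();
      int ax, ay, az;
      off_decode(o, ax, ay, az);
      for (int t = 0; t < 27; ++t) {
        if (!in18[t] || nb[t] || seen[t]) continue;
        int bx, by, bz;
        off_decode(t, bx, by, bz);
        if (std::abs(ax - bx) + std::abs(ay - by) + std::abs(az - bz) == 1) {
          seen[t] = true;
          st.push_back(t);
        }
      }
    }
  }
  return comps;
}

static inline bool is_simple(const bool nb[27]) {
  return fg26_components(nb) == 1 && bg6_components(nb) == 1;
}

// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if ((int)mask.size() != n) stop("mask length does not match grid dimensions");
  std::vector<char> m(n);
  for (int p = 0; p < n; ++p) m[p] = mask[p] ? 1 : 0;

  // face-neighbor offsets for the 6 directional subiterations: U D N S E W
  const int dirs[6][3] = {{0, 0, 1},  {0, 0, -1}, {0, 1, 0},
                          {0, -1, 0}, {1, 0, 0},  {-1, 0, 0}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<int> cand;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            const int p = idx3(i, j, k, nx, ny);
            if (!m[p]) continue;
            const int ii = i + dirs[d][0], jj = j + dirs[d][1],
                      kk = k + dirs[d][2];
            const bool nbg =
                (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
                 kk >= nz) ||
                !m[idx3(ii, jj, kk, nx, ny)];
            if (!nbg) continue;  // not a border point in this direction
            fill_nb(m, i, j, k, nx, ny, nz, nb);
            if (n26_count(nb) == 1) continue;  // endpoint: keep
            if (is_simple(nb)) cand.push_back(p);
          }
      // sequential deletion with re-check preserves topology
      for (int p : cand) {
        const int i = p % nx, j = (p / nx) % ny, k = p / (nx * ny);
        fill_nb(m, i, j, k, nx, ny, nz, nb);
        if (n26_count(nb) == 1) continue;
        if (is_simple(nb)) {
          m[p] = 0;
          changed = true;
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }

  LogicalVector out(n);
  for (int p = 0; p < n; ++p) out[p] = m[p] != 0;
  out.attr("dim") = dim;
  return out;
}
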