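#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Volumes are stored z-fastest? No: R arrays are column-major with dims
// (z, y, x), so z is the fastest-varying index. idx = z + nz*(y + ny*x).

static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z = (int)(v % nz);
      R_xlen_t r = v / nz;
      int y = (int)(r % ny);
      int x = (int)(r / ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t u = vidx(zz, yy, xx, nz, ny);
            if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
          }
    }
  }
  return lab;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher) with
// anisotropic sample spacing h.
static void dt1d(std::vector<double>& f, std::vector<double>& d, double h) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; zb[0] = -INF; zb[1] = INF; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h * h * q * q) - (f[p] + h * h * p * p)) /
          (2.0 * h * (q - p));
      if (s > zb[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (zb[k + 1] < h * q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (um) from each foreground voxel to the nearest
// background voxel, with physical voxel spacing (z, y, x).
// Image faces are NOT treated as background.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  out.attr("dim") = dims;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = out[vidx(z, y, x, nz, ny)];
      dt1d(f, d, spacing[0]);
      for (int z = 0; z < nz; ++z) out[vidx(z, y, x, nz, ny)] = d[z];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = out[vidx(z, y, x, nz, ny)];
      dt1d(f, d, spacing[1]);
      for (int y = 0; y < ny; ++y) out[vidx(z, y, x, nz, ny)] = d[y];
    }
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = out[vidx(z, y, x, nz, ny)];
      dt1d(f, d, spacing[2]);
      for (int x = 0; x < nx; ++x) out[vidx(z, y, x, nz, ny)] = d[x];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

struct WsNode {
  double cost;
  unsigned long long order;
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.cost != b.cost) return a.cost > b.cost; // min-heap on cost
    return a.order > b.order;                     // FIFO tie-break
  }
};

// Seeded watershed: grows seed labels over mask in order of increasing
// cost (priority flood, 6-connectivity). Deterministic for fixed input.
// [[Rcpp::export(name = ".watershed3d_cpp")]]
IntegerVector watershed3d_cpp(NumericVector cost, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  unsigned long long counter = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] > 0) {
      lab[i] = seeds[i];
      pq.push(WsNode{cost[i], counter++, i});
    }
  }
  const int dz6[6] = {-1, 1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, -1, 1, 0, 0};
  const int dx6[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    R_xlen_t v = nd.idx;
    int z = (int)(v % nz);
    R_xlen_t r = v / nz;
    int y = (int)(r % ny);
    int x = (int)(r / ny);
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz6[k], yy = y + dy6[k], xx = x + dx6[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t u = vidx(zz, yy, xx, nz, ny);
      if (!mask[u] || lab[u]) continue;
      lab[u] = lab[v];
      pq.push(WsNode{std::max(cost[u], nd.cost), counter++, u});
    }
  }
  return lab;
}

// Plateau-tolerant 26-neighbourhood local maxima of x over mask.
// [[Rcpp::export(name = ".localmax3d_cpp")]]
LogicalVector localmax3d_cpp(NumericVector x, LogicalVector mask,
                             IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n, FALSE);
  out.attr("dim") = dims;
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    int z = (int)(v % nz);
    R_xlen_t r = v / nz;
    int y = (int)(r % ny);
    int xq = (int)(r / ny);
    bool ismax = true;
    for (int dz = -1; dz <= 1 && ismax; ++dz)
      for (int dy = -1; dy <= 1 && ismax; ++dy)
        for (int dx = -1; dx <= 1 && ismax; ++dx) {
          if (!dz && !dy && !dx) continue;
          int zz = z + dz, yy = y + dy, xx = xq + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          if (x[vidx(zz, yy, xx, nz, ny)] > x[v]) ismax = false;
        }
    out[v] = ismax;
  }
  return out;
}
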