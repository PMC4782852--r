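// Voxel-graph primitives for central luminal line extraction:
//  - exact Euclidean distance transform (Felzenszwalb & Huttenlocher,
//    separable lower-envelope algorithm, anisotropic spacing)
//  - Dijkstra shortest path on the 26-connected foreground graph with
//    medialness-weighted edge costs
//  - flood fill for connected-component diagnostics
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform along a line with sample spacing w (mm);
// f holds finite squared distances (the caller clamps against the grid
// boundary first, so no sentinel infinities remain).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double w) {
  double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from each voxel to the nearest background
// voxel or grid face; background voxels get 0.
// [[Rcpp::export(name = ".edt_3d")]]
NumericVector edt_3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass (clamped against the grid faces so a tube touching the volume edge
  // does not gain spurious medialness there)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t off = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        double db = spacing[0] * (std::min(i, nx - 1 - i) + 1);
        f[i] = std::min(g[off + i], db * db);
      }
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) g[off + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        double db = spacing[1] * (std::min(j, ny - 1 - j) + 1);
        f[j] = std::min(g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)], db * db);
      }
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) {
        double db = spacing[2] * (std::min(k, nz - 1 - k) + 1);
        f[k] = std::min(g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)], db * db);
      }
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Dijkstra on the 26-connected foreground graph.
// Edge cost between adjacent foreground voxels a, b:
//   step_mm(a,b) * (c(a) + c(b)) / 2  with  c(v) = 1 / (1 + dt[v])^2
// which draws the path onto the medial axis (large distance-to-boundary).
// start/end are 0-based linear indices; returns the 0-based path or an empty
// vector if end is unreachable from start.
// [[Rcpp::export(name = ".dijkstra_medial_path")]]
IntegerVector dijkstra_medial_path(LogicalVector mask, NumericVector dt,
                                   IntegerVector dims, NumericVector spacing,
                                   int start, int end) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> dist(n, INF);
  std::vector<int> prev(n, -1);
  std::vector<double> ncost(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double w = 1.0 + dt[i];
    ncost[i] = 1.0 / (w * w);
  }
  std::vector<int> di, dj, dk;
  std::vector<double> step;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
        double sx = a * spacing[0], sy = b * spacing[1], sz = c * spacing[2];
        step.push_back(std::sqrt(sx * sx + sy * sy + sz * sz));
      }
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[start] = 0.0;
  pq.push(QE(0.0, start));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    if (u == end) break;
    int k = u / (nx * ny);
    int rem = u - k * nx * ny;
    int j = rem / nx;
    int i = rem - j * nx;
    for (size_t m = 0; m < di.size(); ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      int w = ii + nx * (jj + ny * kk);
      if (!mask[w]) continue;
      double nd = dist[u] + step[m] * 0.5 * (ncost[u] + ncost[w]);
      if (nd < dist[w]) {
        dist[w] = nd;
        prev[w] = u;
        pq.push(QE(nd, w));
      }
    }
  }
  if (dist[end] == INF) return IntegerVector(0);
  std::vector<int> path;
  for (int u = end; u != -1; u = prev[u]) path.push_back(u);
  std::reverse(path.begin(), path.end());
  return wrap(path);
}

// 26-connected foreground component containing `seed` (0-based) as a mask.
// [[Rcpp::export(name = ".component_mask")]]
LogicalVector component_mask(LogicalVector mask, IntegerVector dims, int seed) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector seen(n);
  if (!mask[seed]) return seen;
  std::vector<int> stack;
  stack.push_back(seed);
  seen[seed] = true;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    int k = u / (nx * ny);
    int rem = u - k * nx * ny;
    int j = rem / nx;
    int i = rem - j * nx;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          int ii = i + a, jj = j + b, kk = k + c;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          int w = ii + nx * (jj + ny * kk);
          if (mask[w] && !seen[w]) { seen[w] = true; stack.push_back(w); }
        }
  }
  return seen;
}

// Size of the 26-connected foreground component containing `seed` (0-based).
// [[Rcpp::export(name = ".component_size")]]
int component_size(LogicalVector mask, IntegerVector dims, int seed) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (!mask[seed]) return 0;
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  stack.push_back(seed);
  seen[seed] = 1;
  int count = 0;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    ++count;
    int k = u / (nx * ny);
    int rem = u - k * nx * ny;
    int j = rem / nx;
    int i = rem - j * nx;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          int ii = i + a, jj = j + b, kk = k + c;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          int w = ii + nx * (jj + ny * kk);
          if (mask[w] && !seen[w]) { seen[w] = 1; stack.push_back(w); }
        }
  }
  return count;
}
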