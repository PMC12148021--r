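#include <Rcpp.h>
#include <vector>
#include <functional>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Separable 1-D convolution along one axis of an n-D array (column-major),
// symmetric (half-sample) reflection at the boundaries. Used to build n-D
// Gaussian smoothing with per-axis sigmas in voxel units.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector x, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nd = dim.size();
  if (axis < 0 || axis >= nd) stop("axis out of range");
  const int n = dim[axis];
  const int kr = (kernel.size() - 1) / 2;
  if ((int)kernel.size() != 2 * kr + 1) stop("kernel length must be odd");

  std::vector<R_xlen_t> stride(nd);
  stride[0] = 1;
  for (int d = 1; d < nd; ++d) stride[d] = stride[d - 1] * dim[d - 1];
  R_xlen_t total = stride[nd - 1] * dim[nd - 1];
  if (total != x.size()) stop("dim does not match data length");

  NumericVector out(total);
  const R_xlen_t s = stride[axis];
  // number of independent lines and how to enumerate their base offsets
  R_xlen_t inner = s;                    // product of dims before axis
  R_xlen_t outer = total / (s * n);      // product of dims after axis
  std::vector<double> line(n);

  for (R_xlen_t o = 0; o < outer; ++o) {
    for (R_xlen_t i = 0; i < inner; ++i) {
      R_xlen_t base = o * s * n + i;
      for (int j = 0; j < n; ++j) line[j] = x[base + (R_xlen_t)j * s];
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        for (int k = -kr; k <= kr; ++k) {
          int idx = j + k;
          if (idx < 0) idx = -idx - 1;            // reflect
          else if (idx >= n) idx = 2 * n - idx - 1;
          if (idx < 0) idx = 0; if (idx >= n) idx = n - 1; // tiny-axis guard
          acc += kernel[k + kr] * line[idx];
        }
        out[base + (R_xlen_t)j * s] = acc;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope-of-parabolas, one pass per axis). feature marks the voxels
// at distance zero; spacing gives the physical voxel size per axis.
// Returns squared distances in physical units.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double s, std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  // lower envelope over the finite parabolas only
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * s;
    while (k >= 0) {
      double xv = v[k] * s;
      double sp = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (k >= 1 && sp <= z[k]) { --k; continue; }
      z[k + 1] = sp;
      break;
    }
    ++k;
    v[k] = q;
    if (k == 0) z[0] = -INF;
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite parabola on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[j + 1] < xq) ++j;
    double xv = v[j] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  const int nd = dim.size();
  if ((int)spacing.size() != nd) stop("spacing length must match dim");
  std::vector<R_xlen_t> stride(nd);
  stride[0] = 1;
  for (int d = 1; d < nd; ++d) stride[d] = stride[d - 1] * dim[d - 1];
  R_xlen_t total = stride[nd - 1] * dim[nd - 1];
  if (total != feature.size()) stop("dim does not match data length");

  const double INF = std::numeric_limits<double>::infinity();
  NumericVector D(total);
  for (R_xlen_t i = 0; i < total; ++i) D[i] = feature[i] ? 0.0 : INF;

  int nmax = *std::max_element(dim.begin(), dim.end());
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int a = 0; a < nd; ++a) {
    const int n = dim[a];
    const R_xlen_t s = stride[a];
    R_xlen_t inner = s;
    R_xlen_t outer = total / (s * n);
    for (R_xlen_t o = 0; o < outer; ++o) {
      for (R_xlen_t i = 0; i < inner; ++i) {
        R_xlen_t base = o * s * n + i;
        bool any = false;
        for (int j = 0; j < n; ++j) {
          f[j] = D[base + (R_xlen_t)j * s];
          if (f[j] < INF) any = true;
        }
        if (!any) continue;
        dt1d(f, d, n, spacing[a], v, z);
        for (int j = 0; j < n; ++j) D[base + (R_xlen_t)j * s] = d[j];
      }
    }
  }
  return D;
}

// ---------------------------------------------------------------------------
// Tolerance-merging watershed on an n-D array (2-D or 3-D), full (8/26)
// connectivity. Voxels with mask == TRUE are flooded in order of decreasing
// intensity; a growing region whose summit rises less than `tolerance` above
// the contact point with a stronger region is merged into it. Boundary voxels
// between surviving regions are assigned to the region of their brightest
// already-labelled neighbour. Deterministic: ties broken by linear index.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_tolerance_watershed(NumericVector x, IntegerVector dim,
                                      double tolerance, LogicalVector mask) {
  const int nd = dim.size();
  if (nd != 2 && nd != 3) stop("only 2-D and 3-D arrays are supported");
  std::vector<R_xlen_t> stride(nd);
  stride[0] = 1;
  for (int d = 1; d < nd; ++d) stride[d] = stride[d - 1] * dim[d - 1];
  R_xlen_t total = stride[nd - 1] * dim[nd - 1];
  if (total != x.size() || total != mask.size()) stop("dim mismatch");

  // neighbour stencil in coordinate deltas
  std::vector<std::vector<int>> nb;
  {
    std::vector<int> lo(nd, -1), hi(nd, 1), cur(nd, -1);
    while (true) {
      bool allz = true;
      for (int d = 0; d < nd; ++d) if (cur[d] != 0) { allz = false; break; }
      if (!allz) nb.push_back(cur);
      int d = 0;
      while (d < nd && cur[d] == hi[d]) { cur[d] = lo[d]; ++d; }
      if (d == nd) break;
      ++cur[d];
    }
  }

  std::vector<R_xlen_t> order;
  order.reserve(total / 4);
  for (R_xlen_t i = 0; i < total; ++i) if (mask[i]) order.push_back(i);
  std::stable_sort(order.begin(), order.end(),
                   [&](R_xlen_t a, R_xlen_t b) {
                     if (x[a] != x[b]) return x[a] > x[b];
                     return a < b;
                   });

  std::vector<int> parent;           // union-find over region ids
  std::vector<double> summit;        // summit intensity per region root
  std::vector<int> region(total, -1);

  std::function<int(int)> find = [&](int r) {
    while (parent[r] != r) { parent[r] = parent[parent[r]]; r = parent[r]; }
    return r;
  };

  std::vector<int> coord(nd);
  std::vector<int> roots;
  roots.reserve(32);

  for (R_xlen_t oi = 0; oi < (R_xlen_t)order.size(); ++oi) {
    R_xlen_t v = order[oi];
    // decode coordinates
    R_xlen_t rem = v;
    for (int d = nd - 1; d >= 0; --d) { coord[d] = (int)(rem / stride[d]); rem %= stride[d]; }

    roots.clear();
    double best_nb_val = -std::numeric_limits<double>::infinity();
    R_xlen_t best_nb = -1;
    for (size_t k = 0; k < nb.size(); ++k) {
      R_xlen_t w = v;
      bool ok = true;
      for (int d = 0; d < nd; ++d) {
        int c = coord[d] + nb[k][d];
        if (c < 0 || c >= dim[d]) { ok = false; break; }
        w += (R_xlen_t)nb[k][d] * stride[d];
      }
      if (!ok || region[w] < 0) continue;
      int r = find(region[w]);
      if (std::find(roots.begin(), roots.end(), r) == roots.end())
        roots.push_back(r);
      if (x[w] > best_nb_val || (x[w] == best_nb_val && w < best_nb)) {
        best_nb_val = x[w];
        best_nb = w;
      }
    }

    if (roots.empty()) {
      int id = (int)parent.size();
      parent.push_back(id);
      summit.push_back(x[v]);
      region[v] = id;
      continue;
    }

    // strongest region: highest summit, tie -> smallest root id
    int best = roots[0];
    for (size_t k = 1; k < roots.size(); ++k) {
      int r = roots[k];
      if (summit[r] > summit[best] || (summit[r] == summit[best] && r < best))
        best = r;
    }
    // merge weak regions (summit prominence below tolerance) into strongest
    for (size_t k = 0; k < roots.size(); ++k) {
      int r = roots[k];
      if (r == best) continue;
      if (summit[r] - x[v] < tolerance) {
        parent[r] = best;
        if (summit[best] < summit[r]) summit[best] = summit[r];
      }
    }
    region[v] = find(region[best_nb]);
  }

  // contiguous labels in flood order
  IntegerVector out(total);
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  for (R_xlen_t oi = 0; oi < (R_xlen_t)order.size(); ++oi) {
    R_xlen_t v = order[oi];
    int r = find(region[v]);
    if (newlab[r] == 0) newlab[r] = ++next;
    out[v] = newlab[r];
  }
  return out;
}
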