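// Low-level voxel-grid operations shared by the detection pipeline.
// All arrays are column-major with linear index i1 + d1*(i2 + d2*i3), 0-based
// internally; exported coordinates are 1-based to match R indexing.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline R_xlen_t lin(int i, int j, int k, int d1, int d2) {
  return (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * k);
}

// Neighbourhood offsets for 6- or 26-connectivity.
static std::vector<std::array<int,3>> neigh_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  if (connectivity == 6) {
    off = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dx || dy || dz) off.push_back({{dx,dy,dz}});
  }
  return off;
}

// [[Rcpp::export]]
NumericVector cpp_median_filter3d(NumericVector v, IntegerVector dim,
                                  IntegerVector radius) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int r1 = radius[0], r2 = radius[1], r3 = radius[2];
  NumericVector out(v.size());
  std::vector<double> win;
  win.reserve((size_t)(2*r1+1)*(2*r2+1)*(2*r3+1));
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        win.clear();
        for (int dz = -r3; dz <= r3; ++dz) {
          int kk = clampi(k+dz, 0, d3-1);
          for (int dy = -r2; dy <= r2; ++dy) {
            int jj = clampi(j+dy, 0, d2-1);
            for (int dx = -r1; dx <= r1; ++dx) {
              int ii = clampi(i+dx, 0, d1-1);
              win.push_back(v[lin(ii,jj,kk,d1,d2)]);
            }
          }
        }
        size_t m = win.size() / 2;
        std::nth_element(win.begin(), win.begin()+m, win.end());
        double med = win[m];
        if (win.size() % 2 == 0) {
          std::nth_element(win.begin(), win.begin()+m-1, win.begin()+m);
          med = 0.5 * (med + win[m-1]);
        }
        out[lin(i,j,k,d1,d2)] = med;
      }
  return out;
}

// Separable 1D convolution along `axis` (1..3) with replicate padding.
// Kernel length must be odd; kernel[half] multiplies the centre voxel.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector v, IntegerVector dim,
                                NumericVector kernel, int axis) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int nk = kernel.size(), half = nk / 2;
  NumericVector out(v.size());
  int n[3] = {d1, d2, d3};
  int len = n[axis-1];
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int pos[3] = {i, j, k};
        double acc = 0.0;
        for (int t = -half; t <= half; ++t) {
          int q[3] = {pos[0], pos[1], pos[2]};
          q[axis-1] = clampi(pos[axis-1] + t, 0, len - 1);
          acc += kernel[t + half] * v[lin(q[0], q[1], q[2], d1, d2)];
        }
        out[lin(i,j,k,d1,d2)] = acc;
      }
  return out;
}

// Running min/max over a window of half-width `radius` along `axis`.
// [[Rcpp::export]]
NumericVector cpp_minmax_axis(NumericVector v, IntegerVector dim,
                              int radius, int axis, bool do_max) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n[3] = {d1, d2, d3};
  int len = n[axis-1];
  NumericVector out(v.size());
  // process each 1D line independently
  int step = (axis == 1) ? 1 : (axis == 2 ? d1 : d1*d2);
  int nlines1, nlines2, s1, s2;
  if (axis == 1)      { nlines1 = d2; nlines2 = d3; s1 = d1; s2 = d1*d2; }
  else if (axis == 2) { nlines1 = d1; nlines2 = d3; s1 = 1;  s2 = d1*d2; }
  else                { nlines1 = d1; nlines2 = d2; s1 = 1;  s2 = d1; }
  std::vector<double> line(len);
  for (int b = 0; b < nlines2; ++b)
    for (int a = 0; a < nlines1; ++a) {
      R_xlen_t base = (R_xlen_t)a*s1 + (R_xlen_t)b*s2;
      for (int t = 0; t < len; ++t) line[t] = v[base + (R_xlen_t)t*step];
      for (int t = 0; t < len; ++t) {
        int lo = std::max(0, t - radius), hi = std::min(len-1, t + radius);
        double acc = line[lo];
        for (int u = lo+1; u <= hi; ++u)
          acc = do_max ? std::max(acc, line[u]) : std::min(acc, line[u]);
        out[base + (R_xlen_t)t*step] = acc;
      }
    }
  return out;
}

// Grayscale maximum filter over an ellipsoidal (or box) neighbourhood given
// by per-axis radii in voxels.
// [[Rcpp::export]]
NumericVector cpp_max_filter(NumericVector v, IntegerVector dim,
                             NumericVector radius, bool box) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int r1 = (int)std::floor(radius[0]), r2 = (int)std::floor(radius[1]),
      r3 = (int)std::floor(radius[2]);
  std::vector<std::array<int,3>> off;
  for (int dz = -r3; dz <= r3; ++dz)
    for (int dy = -r2; dy <= r2; ++dy)
      for (int dx = -r1; dx <= r1; ++dx) {
        if (!box) {
          double e = 0.0;
          if (radius[0] > 0) e += (double)dx*dx/(radius[0]*radius[0]); else if (dx) continue;
          if (radius[1] > 0) e += (double)dy*dy/(radius[1]*radius[1]); else if (dy) continue;
          if (radius[2] > 0) e += (double)dz*dz/(radius[2]*radius[2]); else if (dz) continue;
          if (e > 1.0 + 1e-12) continue;
        }
        off.push_back({{dx,dy,dz}});
      }
  NumericVector out(v.size());
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double acc = -std::numeric_limits<double>::infinity();
        for (auto &o : off) {
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
            continue;
          double val = v[lin(ii,jj,kk,d1,d2)];
          if (val > acc) acc = val;
        }
        out[lin(i,j,k,d1,d2)] = acc;
      }
  return out;
}

// Local peaks: voxel p (inside mask) is a peak iff no neighbour q within the
// ellipsoidal radius has v[q] > v[p], and any tied neighbour is
// lexicographically (x1,x2,x3) larger than p. Returns 1-based coordinates.
// [[Rcpp::export]]
IntegerMatrix cpp_detect_peaks(NumericVector v, IntegerVector dim,
                               NumericVector radius, LogicalVector mask) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int r1 = (int)std::floor(radius[0]), r2 = (int)std::floor(radius[1]),
      r3 = (int)std::floor(radius[2]);
  std::vector<std::array<int,3>> off;
  for (int dz = -r3; dz <= r3; ++dz)
    for (int dy = -r2; dy <= r2; ++dy)
      for (int dx = -r1; dx <= r1; ++dx) {
        if (!dx && !dy && !dz) continue;
        double e = 0.0;
        if (radius[0] > 0) e += (double)dx*dx/(radius[0]*radius[0]); else if (dx) continue;
        if (radius[1] > 0) e += (double)dy*dy/(radius[1]*radius[1]); else if (dy) continue;
        if (radius[2] > 0) e += (double)dz*dz/(radius[2]*radius[2]); else if (dz) continue;
        if (e > 1.0 + 1e-12) continue;
        off.push_back({{dx,dy,dz}});
      }
  std::vector<std::array<int,3>> peaks;
  bool use_mask = mask.size() == v.size();
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t p = lin(i,j,k,d1,d2);
        if (use_mask && !mask[p]) continue;
        double vp = v[p];
        bool ok = true;
        for (auto &o : off) {
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
            continue;
          double vq = v[lin(ii,jj,kk,d1,d2)];
          if (vq > vp) { ok = false; break; }
          if (vq == vp) {
            // lexicographic order on (x1, x2, x3)
            bool q_smaller = (ii < i) || (ii == i && (jj < j || (jj == j && kk < k)));
            if (q_smaller) { ok = false; break; }
          }
        }
        if (ok) peaks.push_back({{i+1, j+1, k+1}});
      }
  IntegerMatrix out(peaks.size(), 3);
  for (size_t t = 0; t < peaks.size(); ++t)
    for (int c = 0; c < 3; ++c) out(t, c) = peaks[t][c];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  auto off = neigh_offsets(connectivity);
  IntegerVector lab(mask.size());
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = p % d1, j = (p / d1) % d2, k = p / ((R_xlen_t)d1*d2);
      for (auto &o : off) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
          continue;
        R_xlen_t q = lin(ii,jj,kk,d1,d2);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

struct FloodEntry {
  double val; long long ord; R_xlen_t idx; int lab;
};
struct FloodCmp {
  bool operator()(const FloodEntry &a, const FloodEntry &b) const {
    if (a.val != b.val) return a.val < b.val;  // higher value first
    return a.ord > b.ord;                      // FIFO among ties
  }
};

// Seeded grayscale watershed: flood the intensity landscape downhill from
// the seeds; each masked voxel joins the catchment basin of one seed.
// [[Rcpp::export]]
IntegerVector cpp_seeded_watershed(NumericVector v, IntegerVector dim,
                                   IntegerVector seed_labels,
                                   LogicalVector mask, int connectivity) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  auto off = neigh_offsets(connectivity);
  IntegerVector lab = clone(seed_labels);
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCmp> pq;
  long long ord = 0;
  for (R_xlen_t p = 0; p < lab.size(); ++p)
    if (lab[p] > 0) pq.push({v[p], ord++, p, lab[p]});
  while (!pq.empty()) {
    FloodEntry e = pq.top(); pq.pop();
    int i = e.idx % d1, j = (e.idx / d1) % d2, k = e.idx / ((R_xlen_t)d1*d2);
    for (auto &o : off) {
      int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
        continue;
      R_xlen_t q = lin(ii,jj,kk,d1,d2);
      if (mask[q] && lab[q] == 0) {
        lab[q] = e.lab;
        pq.push({v[q], ord++, q, e.lab});
      }
    }
  }
  return lab;
}

static const double DT_INF = 1e20;

static void dt1d(std::vector<double> &f, std::vector<double> &d, double s) {
  int n = f.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double POS = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = NEG; z[1] = POS;
  for (int q = 1; q < n; ++q) {
    double xq = q * s, sint = 0.0;
    while (true) {
      double xv = v[k] * s;
      sint = ((f[q] + xq*xq) - (f[v[k]] + xv*xv)) / (2*xq - 2*xv);
      if (k > 0 && sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = sint; z[k+1] = POS;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k+1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance transform (distance in physical units
// to the nearest false voxel), Felzenszwalb-Huttenlocher separable scheme.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<double> dist(n);
  for (R_xlen_t p = 0; p < n; ++p) dist[p] = mask[p] ? DT_INF : 0.0;
  std::vector<double> f, g;
  // pass along each axis
  for (int axis = 0; axis < 3; ++axis) {
    int nd[3] = {d1, d2, d3};
    int len = nd[axis];
    if (len == 1) continue;
    R_xlen_t step = (axis == 0) ? 1 : (axis == 1 ? d1 : (R_xlen_t)d1*d2);
    int nA = (axis == 0) ? d2 : d1;
    int nB = (axis == 2) ? d2 : d3;
    R_xlen_t sA = (axis == 0) ? d1 : 1;
    R_xlen_t sB = (axis == 2) ? d1 : (R_xlen_t)d1*d2;
    f.assign(len, 0.0); g.assign(len, 0.0);
    for (int b = 0; b < nB; ++b)
      for (int a = 0; a < nA; ++a) {
        R_xlen_t base = a*sA + b*sB;
        for (int t = 0; t < len; ++t) f[t] = dist[base + t*step];
        dt1d(f, g, spacing[axis]);
        for (int t = 0; t < len; ++t) dist[base + t*step] = g[t];
      }
  }
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p)
    out[p] = dist[p] >= DT_INF ? R_PosInf : std::sqrt(dist[p]);
  return out;
}

struct DijkEntry { double d; long long ord; R_xlen_t idx; int lab; };
struct DijkCmp {
  bool operator()(const DijkEntry &a, const DijkEntry &b) const {
    if (a.d != b.d) return a.d > b.d;   // smaller distance first
    return a.ord > b.ord;
  }
};

// Assign every unlabeled voxel of `domain` the label of the geodesically
// nearest labeled voxel (multi-source Dijkstra, physical step lengths).
// [[Rcpp::export]]
IntegerVector cpp_nearest_label(IntegerVector labels, IntegerVector dim,
                                NumericVector spacing, LogicalVector domain) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  auto off = neigh_offsets(26);
  std::vector<double> w(off.size());
  for (size_t t = 0; t < off.size(); ++t)
    w[t] = std::sqrt(std::pow(off[t][0]*spacing[0], 2) +
                     std::pow(off[t][1]*spacing[1], 2) +
                     std::pow(off[t][2]*spacing[2], 2));
  IntegerVector lab = clone(labels);
  std::vector<double> dist(lab.size(), DT_INF);
  std::priority_queue<DijkEntry, std::vector<DijkEntry>, DijkCmp> pq;
  long long ord = 0;
  for (R_xlen_t p = 0; p < lab.size(); ++p)
    if (lab[p] > 0 && domain[p]) { dist[p] = 0.0; pq.push({0.0, ord++, p, lab[p]}); }
  while (!pq.empty()) {
    DijkEntry e = pq.top(); pq.pop();
    if (e.d > dist[e.idx]) continue;
    int i = e.idx % d1, j = (e.idx / d1) % d2, k = e.idx / ((R_xlen_t)d1*d2);
    for (size_t t = 0; t < off.size(); ++t) {
      int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
      if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
        continue;
      R_xlen_t q = lin(ii,jj,kk,d1,d2);
      if (!domain[q] || labels[q] > 0) continue;
      double nd = e.d + w[t];
      if (nd < dist[q]) {
        dist[q] = nd; lab[q] = e.lab;
        pq.push({nd, ord++, q, e.lab});
      }
    }
  }
  return lab;
}
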