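#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian blur with reflect-at-border padding.
// [[Rcpp::export]]
NumericMatrix blur_gaussian_cpp(const NumericMatrix& img, int ksize, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int half = ksize / 2;
  std::vector<double> w(ksize);
  double s = 0.0;
  for (int i = 0; i < ksize; ++i) {
    double d = i - half;
    w[i] = std::exp(-0.5 * d * d / (sigma * sigma));
    s += w[i];
  }
  for (int i = 0; i < ksize; ++i) w[i] /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = 0; i < ksize; ++i) {
        int rr = r + i - half;
        if (rr < 0) rr = -rr;                 // reflect
        if (rr >= nr) rr = 2 * nr - rr - 2;
        acc += w[i] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  // along cols (horizontal)
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      for (int i = 0; i < ksize; ++i) {
        int cc = c + i - half;
        if (cc < 0) cc = -cc;
        if (cc >= nc) cc = 2 * nc - cc - 2;
        acc += w[i] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  return out;
}

// Connected-component labelling; labels assigned in raster-scan order of each
// component's first pixel, so label 1 is the component whose first pixel comes
// earliest in scan order (column-major would differ: we scan row-major).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int dr8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = { 0,-1, 1, 0};
  int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  std::queue<std::pair<int,int> > q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  return lab;
}

static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  // Felzenszwalb & Huttenlocher lower envelope of parabolas; sites with
  // infinite f carry no parabola (all-infinite input stays infinite)
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INFINITY; z[1] = INFINITY;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INFINITY;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from every pixel to the nearest TRUE pixel.
// All-FALSE input gives +Inf everywhere.
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass over columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? 0.0 : INFINITY;
    edt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
  }
  // pass over rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out(r, c);
    edt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = d[c];
  }
  return out;
}

// Zhang-Suen thinning to convergence; returns unit-width 8-connected skeleton.
// [[Rcpp::export]]
LogicalMatrix thin_cpp(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> m(nr * nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) m[r * nc + c] = mask(r, c) ? 1 : 0;
  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int r = 1; r < nr - 1; ++r)
        for (int c = 1; c < nc - 1; ++c) {
          int idx = r * nc + c;
          if (!m[idx]) continue;
          // neighbours p2..p9 clockwise from north
          unsigned char p2 = m[(r - 1) * nc + c],     p3 = m[(r - 1) * nc + c + 1];
          unsigned char p4 = m[r * nc + c + 1],       p5 = m[(r + 1) * nc + c + 1];
          unsigned char p6 = m[(r + 1) * nc + c],     p7 = m[(r + 1) * nc + c - 1];
          unsigned char p8 = m[r * nc + c - 1],       p9 = m[(r - 1) * nc + c - 1];
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(idx);
        }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i) m[kill[i]] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) out(r, c) = m[r * nc + c] != 0;
  return out;
}

// Count of TRUE 8-neighbours per TRUE pixel (0 elsewhere).
// [[Rcpp::export]]
IntegerMatrix neighbor_count_cpp(const LogicalMatrix& skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!skel(r, c)) continue;
      int n = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (skel(rr, cc)) ++n;
        }
      out(r, c) = n;
    }
  return out;
}

// Paint value onto canvas wherever distance to any (x, y) point is <= radius.
// Points are 1-based pixel coordinates (x = column, y = row). Used to render
// strokes (disk stamped at every polyline vertex) and the bead disk.
// [[Rcpp::export]]
NumericMatrix stamp_disks_cpp(NumericMatrix canvas, const NumericVector& xs,
                              const NumericVector& ys, double radius, double value) {
  int nr = canvas.nrow(), nc = canvas.ncol();
  int ri = (int)std::ceil(radius);
  double r2 = radius * radius;
  for (int i = 0; i < xs.size(); ++i) {
    double x = xs[i] - 1.0, y = ys[i] - 1.0;  // 0-based
    int c0 = std::max(0, (int)std::floor(x) - ri), c1 = std::min(nc - 1, (int)std::ceil(x) + ri);
    int r0 = std::max(0, (int)std::floor(y) - ri), r1 = std::min(nr - 1, (int)std::ceil(y) + ri);
    for (int r = r0; r <= r1; ++r)
      for (int c = c0; c <= c1; ++c) {
        double dx = c - x, dy = r - y;
        if (dx * dx + dy * dy <= r2 && canvas(r, c) < value) canvas(r, c) = value;
      }
  }
  return canvas;
}

// TRUE wherever distance to any (x, y) point is <= radius (ground-truth mask).
// [[Rcpp::export]]
LogicalMatrix stamp_mask_cpp(int nrow, int ncol, const NumericVector& xs,
                             const NumericVector& ys, double radius) {
  LogicalMatrix out(nrow, ncol);
  int ri = (int)std::ceil(radius);
  double r2 = radius * radius;
  for (int i = 0; i < xs.size(); ++i) {
    double x = xs[i] - 1.0, y = ys[i] - 1.0;
    int c0 = std::max(0, (int)std::floor(x) - ri), c1 = std::min(ncol - 1, (int)std::ceil(x) + ri);
    int r0 = std::max(0, (int)std::floor(y) - ri), r1 = std::min(nrow - 1, (int)std::ceil(y) + ri);
    for (int r = r0; r <= r1; ++r)
      for (int c = c0; c <= c1; ++c) {
        double dx = c - x, dy = r - y;
        if (dx * dx + dy * dy <= r2) out(r, c) = true;
      }
  }
  return out;
}

// Crossing number: 0->1 transitions in the circular 8-neighbour ring
// (p2..p9,p2). Path pixels have 2, endpoints 1, junctions >= 3 — robust to
// the staircase patterns where the raw neighbour count overcounts.
// [[Rcpp::export]]
IntegerMatrix transition_count_cpp(const LogicalMatrix& skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  const int dr[8] = {-1,-1, 0, 1, 1, 1, 0,-1};
  const int dc[8] = { 0, 1, 1, 1, 0,-1,-1,-1};
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!skel(r, c)) continue;
      int ring[8];
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        ring[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc && skel(rr, cc)) ? 1 : 0;
      }
      int t = 0;
      for (int k = 0; k < 8; ++k)
        if (ring[k] == 0 && ring[(k + 1) % 8] == 1) ++t;
      out(r, c) = t;
    }
  return out;
}

// Reduced skeleton adjacency: 8-bit mask of kept neighbour directions per
// pixel, in the order N,E,S,W,NW,NE,SW,SE. A diagonal edge is dropped when
// either of its two common orthogonal neighbours is itself a skeleton pixel
// (the connection then runs through that pixel). Degrees on this reduced
// graph give the true branch count, immune to staircase overconnectivity.
// [[Rcpp::export]]
IntegerMatrix reduced_adjacency_cpp(const LogicalMatrix& skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  const int dr[8] = {-1, 0, 1, 0, -1, -1, 1, 1};
  const int dc[8] = { 0, 1, 0, -1, -1, 1, -1, 1};
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!skel(r, c)) continue;
      int mask = 0;
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (!skel(rr, cc)) continue;
        if (k >= 4) {
          // common orthogonal neighbours of (r,c) and (rr,cc)
          bool a = skel(rr, c);   // vertical then horizontal
          bool b = skel(r, cc);
          if (a || b) continue;
        }
        mask |= (1 << k);
      }
      out(r, c) = mask;
    }
  return out;
}
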