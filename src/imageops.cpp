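#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Coordinate convention throughout: x = column, y = row, 0-based, origin at
// the top-left pixel center. R matrices are indexed img(row, col).

// Rigid transform: the output image is the input rotated by theta (radians)
// about (cx, cy) and then translated by (u, v). Bilinear interpolation,
// source pixels outside the input are 0.
// [[Rcpp::export]]
NumericMatrix cpp_rigid_transform(NumericMatrix img, double u, double v,
                                  double theta, double cx, double cy) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double ct = std::cos(theta), st = std::sin(theta);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      // inverse map: rotate by -theta about center after undoing translation
      double x = c - u - cx, y = r - v - cy;
      double xs = ct * x + st * y + cx;
      double ys = -st * x + ct * y + cy;
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      double fx = xs - x0, fy = ys - y0;
      double val = 0.0;
      if (x0 >= -1 && x0 < nc && y0 >= -1 && y0 < nr) {
        double v00 = (x0 >= 0 && y0 >= 0) ? img(y0, x0) : 0.0;
        double v10 = (x0 + 1 < nc && y0 >= 0) ? img(y0, x0 + 1) : 0.0;
        double v01 = (x0 >= 0 && y0 + 1 < nr) ? img(y0 + 1, x0) : 0.0;
        double v11 = (x0 + 1 < nc && y0 + 1 < nr) ? img(y0 + 1, x0 + 1) : 0.0;
        val = v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
              v01 * (1 - fx) * fy + v11 * fx * fy;
      }
      out(r, c) = val;
    }
  }
  return out;
}

// Bilinear sampling at arbitrary points; outside -> `fill` (may be NA).
// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericMatrix img, NumericVector xs,
                           NumericVector ys, double fill) {
  int nr = img.nrow(), nc = img.ncol(), n = xs.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double x = xs[k], y = ys[k];
    if (x < 0 || y < 0 || x > nc - 1 || y > nr - 1) {
      out[k] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    if (x0 == nc - 1) x0--;
    if (y0 == nr - 1) y0--;
    double fx = x - x0, fy = y - y0;
    out[k] = img(y0, x0) * (1 - fx) * (1 - fy) +
             img(y0, x0 + 1) * fx * (1 - fy) +
             img(y0 + 1, x0) * (1 - fx) * fy +
             img(y0 + 1, x0 + 1) * fx * fy;
  }
  return out;
}

// Normalized correlation gamma over a grid of integer translations of `mov`
// against `ref` (mov already rotated by the caller). Shifted pixels falling
// outside the frame are 0; means/variances are over the full frame.
// Returns gamma matrix with rows indexing v = vmin..vmax, cols u = umin..umax.
// [[Rcpp::export]]
NumericMatrix cpp_gamma_shift_grid(NumericMatrix ref, NumericMatrix mov,
                                   int umin, int umax, int vmin, int vmax) {
  int nr = ref.nrow(), nc = ref.ncol();
  double n = (double)nr * nc;
  double sref = 0, sref2 = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      sref += ref(r, c);
      sref2 += ref(r, c) * ref(r, c);
    }
  double varref = sref2 - sref * sref / n;
  NumericMatrix out(vmax - vmin + 1, umax - umin + 1);
  for (int v = vmin; v <= vmax; ++v) {
    int r0 = std::max(0, v), r1 = std::min(nr, nr + v);  // rows of output overlap
    for (int u = umin; u <= umax; ++u) {
      int c0 = std::max(0, u), c1 = std::min(nc, nc + u);
      double sm = 0, sm2 = 0, cross = 0;
      for (int c = c0; c < c1; ++c) {
        for (int r = r0; r < r1; ++r) {
          double mv = mov(r - v, c - u);
          sm += mv;
          sm2 += mv * mv;
          cross += ref(r, c) * mv;
        }
      }
      double num = cross - sref * sm / n;
      double den = std::sqrt(varref * (sm2 - sm * sm / n));
      out(v - vmin, u - umin) = (den > 0) ? num / den : NA_REAL;
    }
  }
  return out;
}

// Largest 4-connected foreground component. Returns list(mask, n_components,
// sizes) so the caller can warn about discarded components.
// [[Rcpp::export]]
List cpp_largest_component(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> label(nr * nc, 0);
  int ncomp = 0;
  std::vector<int> sizes;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = c * nr + r;
      if (!mask(r, c) || label[idx]) continue;
      ++ncomp;
      int sz = 0;
      std::queue<int> q;
      q.push(idx);
      label[idx] = ncomp;
      while (!q.empty()) {
        int cur = q.front(); q.pop();
        ++sz;
        int cr = cur % nr, cc = cur / nr;
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int i2 = c2 * nr + r2;
          if (mask(r2, c2) && !label[i2]) {
            label[i2] = ncomp;
            q.push(i2);
          }
        }
      }
      sizes.push_back(sz);
    }
  }
  int best = 0;
  for (int k = 1; k < (int)sizes.size(); ++k)
    if (sizes[k] > sizes[best]) best = k;
  LogicalMatrix out(nr, nc);
  if (ncomp > 0)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        out(r, c) = (label[c * nr + r] == best + 1);
  return List::create(_["mask"] = out, _["n_components"] = ncomp,
                      _["sizes"] = wrap(sizes));
}

// Fill interior holes: flood the background from the border (4-connected);
// unreached background becomes foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside(nr * nc, 0);
  std::queue<int> q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if ((r == 0 || r == nr - 1 || c == 0 || c == nc - 1) && !mask(r, c)) {
        int idx = c * nr + r;
        if (!outside[idx]) {
          outside[idx] = 1;
          q.push(idx);
        }
      }
    }
  }
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    int cr = cur % nr, cc = cur / nr;
    const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
    for (int k = 0; k < 4; ++k) {
      int r2 = cr + dr[k], c2 = cc + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int i2 = c2 * nr + r2;
      if (!mask(r2, c2) && !outside[i2]) {
        outside[i2] = 1;
        q.push(i2);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) || !outside[c * nr + r];
  return out;
}
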