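#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
using namespace Rcpp;

// Ray-casting point-in-polygon. Points exactly on an edge are classified by
// the crossing parity; callers that need "strictly inside" should shrink by
// an epsilon themselves if that matters.
// [[Rcpp::export]]
LogicalVector cpp_point_in_polygon(NumericVector px, NumericVector py,
                                   NumericVector polyx, NumericVector polyy) {
  int n = px.size(), m = polyx.size();
  LogicalVector out(n);
  for (int k = 0; k < n; ++k) {
    double x = px[k], y = py[k];
    bool inside = false;
    for (int i = 0, j = m - 1; i < m; j = i++) {
      double xi = polyx[i], yi = polyy[i], xj = polyx[j], yj = polyy[j];
      if (((yi > y) != (yj > y)) &&
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        inside = !inside;
    }
    out[k] = inside;
  }
  return out;
}

// Minimum distance from each query point to an open polyline, plus the
// arc-length coordinate of the foot of the perpendicular on the polyline.
// Returns an n x 2 matrix: [ ,1] distance, [ ,2] arc length s.
// [[Rcpp::export]]
NumericMatrix cpp_dist_to_polyline(NumericVector px, NumericVector py,
                                   NumericVector lx, NumericVector ly) {
  int n = px.size(), m = lx.size();
  NumericMatrix out(n, 2);
  std::vector<double> cum(m, 0.0);
  for (int i = 1; i < m; ++i) {
    double dx = lx[i] - lx[i - 1], dy = ly[i] - ly[i - 1];
    cum[i] = cum[i - 1] + std::sqrt(dx * dx + dy * dy);
  }
  for (int k = 0; k < n; ++k) {
    double best = R_PosInf, bests = 0.0;
    double x = px[k], y = py[k];
    for (int i = 0; i + 1 < m; ++i) {
      double ax = lx[i], ay = ly[i];
      double bx = lx[i + 1], by = ly[i + 1];
      double dx = bx - ax, dy = by - ay;
      double len2 = dx * dx + dy * dy;
      double t = 0.0;
      if (len2 > 0) {
        t = ((x - ax) * dx + (y - ay) * dy) / len2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
      }
      double qx = ax + t * dx, qy = ay + t * dy;
      double d = std::hypot(x - qx, y - qy);
      if (d < best) {
        best = d;
        bests = cum[i] + t * std::sqrt(len2);
      }
    }
    out(k, 0) = best;
    out(k, 1) = bests;
  }
  return out;
}

// ---- Bowyer-Watson Delaunay triangulation --------------------------------

struct Tri {
  int a, b, c;
  double cx, cy, r2;
  bool alive;
};

static void circumcircle(double ax, double ay, double bx, double by,
                         double cx_, double cy_, double &ox, double &oy,
                         double &r2) {
  double d = 2.0 * (ax * (by - cy_) + bx * (cy_ - ay) + cx_ * (ay - by));
  if (std::fabs(d) < 1e-12) {
    ox = oy = 0;
    r2 = R_PosInf;
    return;
  }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
         c2 = cx_ * cx_ + cy_ * cy_;
  ox = (a2 * (by - cy_) + b2 * (cy_ - ay) + c2 * (ay - by)) / d;
  oy = (a2 * (cx_ - bx) + b2 * (ax - cx_) + c2 * (bx - ax)) / d;
  double dx = ax - ox, dy = ay - oy;
  r2 = dx * dx + dy * dy;
}

// Returns an nt x 3 (1-based) matrix of triangle vertex indices.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(n + 3), py(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = x[i];
    py[i] = y[i];
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) dmax = 1.0;
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  px[n] = midx - 20 * dmax;  py[n] = midy - dmax;
  px[n + 1] = midx;          py[n + 1] = midy + 20 * dmax;
  px[n + 2] = midx + 20 * dmax; py[n + 2] = midy - dmax;

  std::vector<Tri> tris;
  Tri super;
  super.a = n; super.b = n + 1; super.c = n + 2; super.alive = true;
  circumcircle(px[super.a], py[super.a], px[super.b], py[super.b],
               px[super.c], py[super.c], super.cx, super.cy, super.r2);
  tris.push_back(super);

  for (int i = 0; i < n; ++i) {
    std::map<std::pair<int, int>, int> edgecount;
    std::vector<int> bad;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = px[i] - tris[t].cx, dy = py[i] - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2) {
        bad.push_back((int)t);
        int v[3] = {tris[t].a, tris[t].b, tris[t].c};
        for (int e = 0; e < 3; ++e) {
          int u1 = v[e], u2 = v[(e + 1) % 3];
          std::pair<int, int> key(std::min(u1, u2), std::max(u1, u2));
          edgecount[key]++;
        }
      }
    }
    for (size_t b = 0; b < bad.size(); ++b) tris[bad[b]].alive = false;
    for (std::map<std::pair<int, int>, int>::iterator it = edgecount.begin();
         it != edgecount.end(); ++it) {
      if (it->second != 1) continue;  // shared edge, interior to the cavity
      Tri nt;
      nt.a = it->first.first; nt.b = it->first.second; nt.c = i;
      nt.alive = true;
      circumcircle(px[nt.a], py[nt.a], px[nt.b], py[nt.b], px[nt.c], py[nt.c],
                   nt.cx, nt.cy, nt.r2);
      tris.push_back(nt);
    }
  }

  int keep = 0;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n)
      keep++;
  IntegerMatrix out(keep, 3);
  int r = 0;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive || tris[t].a >= n || tris[t].b >= n || tris[t].c >= n)
      continue;
    out(r, 0) = tris[t].a + 1;
    out(r, 1) = tris[t].b + 1;
    out(r, 2) = tris[t].c + 1;
    ++r;
  }
  return out;
}
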