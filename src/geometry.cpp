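#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- polygon primitives ------------------------------------------------

static double signed_area(const std::vector<double>& x,
                          const std::vector<double>& y) {
  const int n = x.size();
  double a = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    a += x[i] * y[j] - x[j] * y[i];
  }
  return 0.5 * a;
}

// [[Rcpp::export]]
double cpp_polygon_area(NumericMatrix pts) {
  const int n = pts.nrow();
  double a = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    a += pts(i, 0) * pts(j, 1) - pts(j, 0) * pts(i, 1);
  }
  return std::fabs(0.5 * a);
}

// Sutherland-Hodgman clip of a convex polygon by the half-plane left of
// the directed edge (ax,ay)->(bx,by).  Subject must be convex and CCW.
static void clip_halfplane(std::vector<double>& px, std::vector<double>& py,
                           double ax, double ay, double bx, double by) {
  const double ex = bx - ax, ey = by - ay;
  std::vector<double> qx, qy;
  const int n = px.size();
  if (n == 0) return;
  qx.reserve(n + 4); qy.reserve(n + 4);
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    // inside = left of CCW edge: cross(b-a, p-a) >= 0
    double c1 = (px[i] - ax) * ey - (py[i] - ay) * ex;
    double c2 = (px[j] - ax) * ey - (py[j] - ay) * ex;
    bool in1 = c1 <= 0.0, in2 = c2 <= 0.0;
    if (in1) { qx.push_back(px[i]); qy.push_back(py[i]); }
    if (in1 != in2) {
      double t = c1 / (c1 - c2);
      qx.push_back(px[i] + t * (px[j] - px[i]));
      qy.push_back(py[i] + t * (py[j] - py[i]));
    }
  }
  px.swap(qx); py.swap(qy);
}

// area of intersection of two triangles (given CCW)
static double tri_tri_inter(const double* tx1, const double* ty1,
                            const double* tx2, const double* ty2) {
  std::vector<double> px(tx1, tx1 + 3), py(ty1, ty1 + 3);
  for (int e = 0; e < 3 && !px.empty(); ++e) {
    int f = (e + 1) % 3;
    clip_halfplane(px, py, tx2[e], ty2[e], tx2[f], ty2[f]);
  }
  if (px.size() < 3) return 0.0;
  return std::fabs(signed_area(px, py));
}

struct FanTri {
  double x[3], y[3];
  int sign;
  double xmin, xmax, ymin, ymax;
};

// decompose a simple polygon into signed fan triangles from vertex 0,
// each normalised to CCW; sign carries orientation so that
// sum_i sign_i * 1_{T_i}(p) = 1 inside the polygon (a.e.)
static void fan_decompose(NumericMatrix P, std::vector<FanTri>& out) {
  const int n = P.nrow();
  std::vector<double> vx(n), vy(n);
  for (int i = 0; i < n; ++i) { vx[i] = P(i, 0); vy[i] = P(i, 1); }
  double orient = signed_area(vx, vy) >= 0 ? 1.0 : -1.0;
  for (int i = 1; i + 1 < n; ++i) {
    double sx[3] = { vx[0], vx[i], vx[i + 1] };
    double sy[3] = { vy[0], vy[i], vy[i + 1] };
    double sa = 0.5 * ((sx[1] - sx[0]) * (sy[2] - sy[0]) -
                       (sx[2] - sx[0]) * (sy[1] - sy[0]));
    if (std::fabs(sa) < 1e-14) continue;
    FanTri t;
    int s = sa >= 0 ? 1 : -1;
    if (s < 0) { // store CCW
      t.x[0] = sx[0]; t.x[1] = sx[2]; t.x[2] = sx[1];
      t.y[0] = sy[0]; t.y[1] = sy[2]; t.y[2] = sy[1];
    } else {
      for (int k = 0; k < 3; ++k) { t.x[k] = sx[k]; t.y[k] = sy[k]; }
    }
    t.sign = (int)(s * orient);
    t.xmin = std::min(std::min(t.x[0], t.x[1]), t.x[2]);
    t.xmax = std::max(std::max(t.x[0], t.x[1]), t.x[2]);
    t.ymin = std::min(std::min(t.y[0], t.y[1]), t.y[2]);
    t.ymax = std::max(std::max(t.y[0], t.y[1]), t.y[2]);
    out.push_back(t);
  }
}

static double inter_area_decomp(const std::vector<FanTri>& A,
                                const std::vector<FanTri>& B) {
  double inter = 0.0;
  for (size_t i = 0; i < A.size(); ++i) {
    for (size_t j = 0; j < B.size(); ++j) {
      const FanTri& a = A[i];
      const FanTri& b = B[j];
      if (a.xmax <= b.xmin || b.xmax <= a.xmin ||
          a.ymax <= b.ymin || b.ymax <= a.ymin) continue;
      double ia = tri_tri_inter(a.x, a.y, b.x, b.y);
      if (ia > 0.0) inter += a.sign * b.sign * ia;
    }
  }
  return inter;
}

// [[Rcpp::export]]
double cpp_polygon_iou(NumericMatrix A, NumericMatrix B) {
  double areaA = cpp_polygon_area(A), areaB = cpp_polygon_area(B);
  if (areaA < 1e-12 || areaB < 1e-12) return 0.0;
  std::vector<FanTri> dA, dB;
  fan_decompose(A, dA);
  fan_decompose(B, dB);
  double inter = inter_area_decomp(dA, dB);
  if (inter < 0.0) inter = 0.0;
  double m = std::min(areaA, areaB);
  if (inter > m) inter = m;
  double uni = areaA + areaB - inter;
  return uni > 0.0 ? inter / uni : 0.0;
}

// ---- point in polygon / rasterization ---------------------------------

static bool point_in_poly(double x, double y, const NumericMatrix& P) {
  const int n = P.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = P(i, 0), yi = P(i, 1), xj = P(j, 0), yj = P(j, 1);
    if (((yi > y) != (yj > y)) &&
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// polys sorted by score descending; id of element i is i+1; later paints
// (higher score) overwrite earlier, so iterate from lowest to highest.
// Coordinates are 0-based pixel units, x = column, y = row.
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize(List polys, int nrow_img, int ncol_img) {
  IntegerMatrix lab(nrow_img, ncol_img);
  const int K = polys.size();
  for (int i = K - 1; i >= 0; --i) {
    NumericMatrix P = polys[i];
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int v = 0; v < P.nrow(); ++v) {
      xmin = std::min(xmin, P(v, 0)); xmax = std::max(xmax, P(v, 0));
      ymin = std::min(ymin, P(v, 1)); ymax = std::max(ymax, P(v, 1));
    }
    int x0 = std::max(0, (int)std::floor(xmin));
    int x1 = std::min(ncol_img - 1, (int)std::ceil(xmax));
    int y0 = std::max(0, (int)std::floor(ymin));
    int y1 = std::min(nrow_img - 1, (int)std::ceil(ymax));
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x)
        if (point_in_poly((double)x, (double)y, P))
          lab(y, x) = i + 1;
  }
  return lab;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_poly(NumericVector x, NumericVector y,
                                 NumericMatrix P) {
  const int n = x.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = point_in_poly(x[i], y[i], P);
  return out;
}

// ---- separable gaussian blur (reflecting borders) ----------------------

// [[Rcpp::export]]
NumericMatrix cpp_blur(NumericMatrix img, double sigma) {
  const int h = img.nrow(), w = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  NumericMatrix tmp(h, w), out(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double v = 0.0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i;
        if (xx < 0) xx = -xx - 1;
        if (xx >= w) xx = 2 * w - xx - 1;
        v += k[i + r] * img(y, xx);
      }
      tmp(y, x) = v;
    }
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double v = 0.0;
      for (int i = -r; i <= r; ++i) {
        int yy = y + i;
        if (yy < 0) yy = -yy - 1;
        if (yy >= h) yy = 2 * h - yy - 1;
        v += k[i + r] * tmp(yy, x);
      }
      out(y, x) = v;
    }
  return out;
}

// ---- radial distances by ray marching ----------------------------------

// fg: logical foreground matrix; px/py 0-based pixel coordinates of query
// points (x = column, y = row).  Ray k points at angle 2*pi*k/n_rays,
// angle 0 = +x, measured toward +y.  Distance = march length to the first
// background sample minus half a step (boundary estimate), in pixels.
// [[Rcpp::export]]
NumericMatrix cpp_radial_dist(LogicalMatrix fg, IntegerVector px,
                              IntegerVector py, int n_rays,
                              double step, double rmax) {
  const int h = fg.nrow(), w = fg.ncol();
  const int n = px.size();
  NumericMatrix out(n, n_rays);
  std::vector<double> cs(n_rays), sn(n_rays);
  for (int k = 0; k < n_rays; ++k) {
    double th = 2.0 * M_PI * k / n_rays;
    cs[k] = std::cos(th); sn[k] = std::sin(th);
  }
  for (int i = 0; i < n; ++i) {
    double x0 = px[i], y0 = py[i];
    for (int k = 0; k < n_rays; ++k) {
      double t = step, r = step / 2.0;
      while (t <= rmax) {
        int xx = (int)std::lround(x0 + t * cs[k]);
        int yy = (int)std::lround(y0 + t * sn[k]);
        if (xx < 0 || yy < 0 || xx >= w || yy >= h || !fg(yy, xx)) {
          r = t - step / 2.0;
          break;
        }
        t += step;
        r = t - step / 2.0;
      }
      out(i, k) = std::max(r, step / 2.0);
    }
  }
  return out;
}

// ---- greedy non-maximum suppression ------------------------------------

// centers (n x 2), radii (n x n_rays), already sorted by score descending.
// Returns logical keep vector.  Exact polygon IoU with bbox prefilter.
// [[Rcpp::export]]
LogicalVector cpp_nms(NumericMatrix centers, NumericMatrix radii,
                      double iou_threshold) {
  const int n = centers.nrow(), m = radii.ncol();
  LogicalVector keep(n);
  std::vector<double> cs(m), sn(m);
  for (int k = 0; k < m; ++k) {
    double th = 2.0 * M_PI * k / m;
    cs[k] = std::cos(th); sn[k] = std::sin(th);
  }
  std::vector<double> rmaxv(n);
  for (int i = 0; i < n; ++i) {
    double r = 0.0;
    for (int k = 0; k < m; ++k) r = std::max(r, radii(i, k));
    rmaxv[i] = r;
  }
  std::vector<int> acc;
  std::vector< std::vector<FanTri> > acc_tris;
  NumericMatrix Pi(m, 2);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) {
      Pi(k, 0) = centers(i, 0) + radii(i, k) * cs[k];
      Pi(k, 1) = centers(i, 1) + radii(i, k) * sn[k];
    }
    bool suppressed = false;
    std::vector<FanTri> di;
    fan_decompose(Pi, di);
    double areaI = cpp_polygon_area(Pi);
    for (size_t a = 0; a < acc.size(); ++a) {
      int j = acc[a];
      double dx = centers(i, 0) - centers(j, 0);
      double dy = centers(i, 1) - centers(j, 1);
      double dd = rmaxv[i] + rmaxv[j];
      if (dx * dx + dy * dy >= dd * dd) continue;
      NumericMatrix Pj(m, 2);
      for (int k = 0; k < m; ++k) {
        Pj(k, 0) = centers(j, 0) + radii(j, k) * cs[k];
        Pj(k, 1) = centers(j, 1) + radii(j, k) * sn[k];
      }
      double areaJ = cpp_polygon_area(Pj);
      double inter = inter_area_decomp(di, acc_tris[a]);
      if (inter < 0) inter = 0;
      double mn = std::min(areaI, areaJ);
      if (inter > mn) inter = mn;
      double uni = areaI + areaJ - inter;
      double iou = uni > 0 ? inter / uni : 0.0;
      if (iou > iou_threshold) { suppressed = true; break; }
    }
    if (!suppressed) {
      keep[i] = true;
      acc.push_back(i);
      acc_tris.push_back(di);
    }
  }
  return keep;
}

// ---- connected components (4-connectivity) -----------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_cc(LogicalMatrix m) {
  const int h = m.nrow(), w = m.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<int> stack;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      if (!m(y, x) || lab(y, x)) continue;
      ++next;
      stack.clear();
      stack.push_back(y * w + x);
      lab(y, x) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int cy = p / w, cx = p % w;
        const int dy[4] = { -1, 1, 0, 0 }, dx[4] = { 0, 0, -1, 1 };
        for (int d = 0; d < 4; ++d) {
          int ny = cy + dy[d], nx = cx + dx[d];
          if (ny < 0 || nx < 0 || ny >= h || nx >= w) continue;
          if (m(ny, nx) && !lab(ny, nx)) {
            lab(ny, nx) = next;
            stack.push_back(ny * w + nx);
          }
        }
      }
    }
  }
  return lab;
}

// ---- dart-throwing placement -------------------------------------------

// Place up to n centers in [margin, w-margin] x [margin, h-margin] such
// that dist(i, j) >= rad[i] + rad[j] + gap.  Uses the R RNG (seedable from
// R).  Returns a k x 2 matrix of the centers actually placed (k <= n).
// [[Rcpp::export]]
NumericMatrix cpp_dart(int n, double w, double h, NumericVector rad,
                       double gap, int max_attempts) {
  std::vector<double> xs, ys;
  xs.reserve(n); ys.reserve(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, rad[i]);
  double cell = 2.0 * rmax + gap;
  int gw = std::max(1, (int)std::ceil(w / cell));
  int gh = std::max(1, (int)std::ceil(h / cell));
  std::vector< std::vector<int> > grid(gw * gh);
  int placed = 0, attempts = 0;
  while (placed < n && attempts < max_attempts) {
    ++attempts;
    double m = rad[placed] + 1.0;
    if (2.0 * m >= w || 2.0 * m >= h) break;
    double x = m + R::unif_rand() * (w - 2.0 * m);
    double y = m + R::unif_rand() * (h - 2.0 * m);
    int gx = std::min(gw - 1, (int)(x / cell));
    int gy = std::min(gh - 1, (int)(y / cell));
    bool ok = true;
    for (int dy = -1; dy <= 1 && ok; ++dy)
      for (int dx = -1; dx <= 1 && ok; ++dx) {
        int nx = gx + dx, ny = gy + dy;
        if (nx < 0 || ny < 0 || nx >= gw || ny >= gh) continue;
        const std::vector<int>& b = grid[ny * gw + nx];
        for (size_t q = 0; q < b.size(); ++q) {
          int j = b[q];
          double ddx = x - xs[j], ddy = y - ys[j];
          double need = rad[placed] + rad[j] + gap;
          if (ddx * ddx + ddy * ddy < need * need) { ok = false; break; }
        }
      }
    if (ok) {
      xs.push_back(x); ys.push_back(y);
      grid[gy * gw + gx].push_back(placed);
      ++placed;
    }
  }
  NumericMatrix out(placed, 2);
  for (int i = 0; i < placed; ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}
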