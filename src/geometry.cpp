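// Planar geometry kernels for the cortical pulling-force model: point-in-polygon,
// first-hit ray casting, per-pole astral forces, the orientation scan with
// per-angle force-balanced centering, and the dense brute-force reference
// scan. Ray directions are fixed in the lab frame and shared by both poles.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

struct Poly {
  std::vector<double> x, y;
  int n;
  bool convex;
  double scale2; // squared bounding-box diagonal, for tolerances
};

static Poly make_poly(const NumericMatrix& V) {
  Poly P;
  P.n = V.nrow();
  P.x.resize(P.n);
  P.y.resize(P.n);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < P.n; ++i) {
    P.x[i] = V(i, 0);
    P.y[i] = V(i, 1);
    xmin = std::min(xmin, P.x[i]); xmax = std::max(xmax, P.x[i]);
    ymin = std::min(ymin, P.y[i]); ymax = std::max(ymax, P.y[i]);
  }
  P.scale2 = (xmax - xmin) * (xmax - xmin) + (ymax - ymin) * (ymax - ymin);
  P.convex = true;
  double tol = -1e-10 * P.scale2;
  for (int i = 0; i < P.n; ++i) {
    int j = (i + 1) % P.n, k = (i + 2) % P.n;
    double c = cross2(P.x[j] - P.x[i], P.y[j] - P.y[i],
                      P.x[k] - P.x[j], P.y[k] - P.y[j]);
    if (c < tol) { P.convex = false; break; }
  }
  return P;
}

// even-odd rule; boundary points are resolved arbitrarily but deterministically
static bool pip(const Poly& P, double px, double py) {
  bool inside = false;
  for (int i = 0, j = P.n - 1; i < P.n; j = i++) {
    if (((P.y[i] > py) != (P.y[j] > py)) &&
        (px < (P.x[j] - P.x[i]) * (py - P.y[i]) / (P.y[j] - P.y[i]) + P.x[i]))
      inside = !inside;
  }
  return inside;
}

static double dist_to_boundary(const Poly& P, double px, double py) {
  double best = R_PosInf;
  for (int i = 0, j = P.n - 1; i < P.n; j = i++) {
    double ex = P.x[i] - P.x[j], ey = P.y[i] - P.y[j];
    double wx = px - P.x[j], wy = py - P.y[j];
    double L2 = ex * ex + ey * ey;
    double t = (L2 > 0) ? (wx * ex + wy * ey) / L2 : 0.0;
    if (t < 0) t = 0; else if (t > 1) t = 1;
    double dx = wx - t * ex, dy = wy - t * ey;
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < best) best = d;
  }
  return best;
}

// first boundary hit along (dx,dy) from (ox,oy); exhaustive over edges,
// correct for any simple polygon (non-convex safe). Returns -1 if no hit.
static double ray_full(const Poly& P, double ox, double oy, double dx, double dy) {
  double tmin = -1.0;
  for (int i = 0, j = P.n - 1; i < P.n; j = i++) {
    double ex = P.x[i] - P.x[j], ey = P.y[i] - P.y[j];
    double denom = cross2(dx, dy, ex, ey);
    if (std::fabs(denom) < 1e-300) continue;
    double wx = P.x[j] - ox, wy = P.y[j] - oy;
    double t = cross2(wx, wy, ex, ey) / denom;
    double s = cross2(wx, wy, dx, dy) / denom;
    if (t > 1e-12 && s >= -1e-12 && s <= 1.0 + 1e-12) {
      if (tmin < 0 || t < tmin) tmin = t;
    }
  }
  return tmin;
}

static inline double pow_int_or_real(double t, double e, int ie) {
  if (ie >= 0) {
    double r = 1.0;
    for (int k = 0; k < ie; ++k) r *= t;
    return r;
  }
  return std::pow(t, e);
}

static inline int int_exponent(double e) {
  double r = std::floor(e + 0.5);
  if (r >= 0 && r <= 16 && std::fabs(e - r) < 1e-12) return (int)r;
  return -1;
}

struct PoleTerms { double Fx, Fy, W; bool ok; };

// Astral terms of one pole: pulling force F = sum_k L_k^beta d_k and total
// microtubule potential W = sum_k L_k^(beta+1)/(beta+1), over the fixed
// lab-frame direction fan. Convex polygons use an ordered sector walk (each
// direction hits exactly one edge); otherwise full edge scans per ray.
static PoleTerms pole_terms(const Poly& P, double ox, double oy,
                            const std::vector<double>& dx,
                            const std::vector<double>& dy,
                            double beta, int ibeta) {
  PoleTerms out = {0.0, 0.0, 0.0, false};
  int m = (int)dx.size();
  double bp1 = beta + 1.0;
  if (P.convex) {
    int n = P.n;
    int i = -1;
    for (int e = 0; e < n; ++e) {
      int j = (e + 1) % n;
      if (cross2(P.x[e] - ox, P.y[e] - oy, dx[0], dy[0]) >= 0 &&
          cross2(dx[0], dy[0], P.x[j] - ox, P.y[j] - oy) > 0) { i = e; break; }
    }
    if (i < 0) return out; // origin outside or degenerate
    for (int k = 0; k < m; ++k) {
      int guard = 0;
      bool found = true;
      while (true) {
        int j = (i + 1) % n;
        if (cross2(P.x[i] - ox, P.y[i] - oy, dx[k], dy[k]) >= 0 &&
            cross2(dx[k], dy[k], P.x[j] - ox, P.y[j] - oy) > 0) break;
        i = (i + 1) % n;
        if (++guard > n) { found = false; break; }
      }
      double t = -1.0;
      if (found) {
        int j = (i + 1) % n;
        double ex = P.x[j] - P.x[i], ey = P.y[j] - P.y[i];
        double denom = cross2(dx[k], dy[k], ex, ey);
        if (std::fabs(denom) > 1e-300)
          t = cross2(P.x[i] - ox, P.y[i] - oy, ex, ey) / denom;
      }
      if (!(t > 0.0) || !std::isfinite(t)) {
        t = ray_full(P, ox, oy, dx[k], dy[k]);
        if (!(t > 0.0)) return out;
      }
      double f = pow_int_or_real(t, beta, ibeta);
      out.Fx += f * dx[k];
      out.Fy += f * dy[k];
      out.W += f * t / bp1;
    }
  } else {
    for (int k = 0; k < m; ++k) {
      double t = ray_full(P, ox, oy, dx[k], dy[k]);
      if (!(t > 0.0)) return out;
      double f = pow_int_or_real(t, beta, ibeta);
      out.Fx += f * dx[k];
      out.Fy += f * dy[k];
      out.W += f * t / bp1;
    }
  }
  out.ok = true;
  return out;
}

static void make_dirs(int n_rays, std::vector<double>& dx, std::vector<double>& dy) {
  dx.resize(n_rays);
  dy.resize(n_rays);
  for (int k = 0; k < n_rays; ++k) {
    double a = 2.0 * M_PI * k / n_rays;
    dx[k] = std::cos(a);
    dy[k] = std::sin(a);
  }
}

struct Placement { bool ok; double Fx, Fy, torque, W, fnorm2; };

// Evaluate one (center, angle) placement: net force on the spindle, torque
// about its center, and total astral potential. Infeasible if a pole is on
// or outside the boundary.
static Placement placement_terms(const Poly& P, double cx, double cy,
                                 double angle_deg, double length,
                                 const std::vector<double>& dx,
                                 const std::vector<double>& dy,
                                 double beta, int ibeta) {
  Placement out = {false, 0, 0, 0, 0, R_PosInf};
  double th = angle_deg * M_PI / 180.0;
  double hx = 0.5 * length * std::cos(th), hy = 0.5 * length * std::sin(th);
  double ax = cx + hx, ay = cy + hy, bx = cx - hx, by = cy - hy;
  if (!pip(P, ax, ay) || !pip(P, bx, by)) return out;
  PoleTerms A = pole_terms(P, ax, ay, dx, dy, beta, ibeta);
  if (!A.ok) return out;
  PoleTerms B = pole_terms(P, bx, by, dx, dy, beta, ibeta);
  if (!B.ok) return out;
  out.ok = true;
  out.Fx = A.Fx + B.Fx;
  out.Fy = A.Fy + B.Fy;
  out.torque = cross2(hx, hy, A.Fx, A.Fy) + cross2(-hx, -hy, B.Fx, B.Fy);
  out.W = A.W + B.W;
  out.fnorm2 = out.Fx * out.Fx + out.Fy * out.Fy;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericMatrix V, NumericMatrix pts) {
  Poly P = make_poly(V);
  int m = pts.nrow();
  LogicalVector out(m);
  for (int i = 0; i < m; ++i) out[i] = pip(P, pts(i, 0), pts(i, 1));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_dist_to_boundary(NumericMatrix V, NumericMatrix pts) {
  Poly P = make_poly(V);
  int m = pts.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) out[i] = dist_to_boundary(P, pts(i, 0), pts(i, 1));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ray_lengths(NumericMatrix V, NumericVector origin, NumericMatrix dirs) {
  Poly P = make_poly(V);
  int m = dirs.nrow();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    double nrm = std::sqrt(dirs(k, 0) * dirs(k, 0) + dirs(k, 1) * dirs(k, 1));
    double t = ray_full(P, origin[0], origin[1], dirs(k, 0) / nrm, dirs(k, 1) / nrm);
    out[k] = (t > 0) ? t : NA_REAL;
  }
  return out;
}

// proper or improper intersection of non-adjacent edges => not simple
// [[Rcpp::export]]
bool cpp_is_simple(NumericMatrix V) {
  Poly P = make_poly(V);
  int n = P.n;
  double eps = 1e-12 * std::sqrt(P.scale2 > 0 ? P.scale2 : 1.0);
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j == i2 || j2 == i) continue; // adjacent edges share a vertex
      double p1x = P.x[i], p1y = P.y[i], p2x = P.x[i2], p2y = P.y[i2];
      double q1x = P.x[j], q1y = P.y[j], q2x = P.x[j2], q2y = P.y[j2];
      double d1 = cross2(q2x - q1x, q2y - q1y, p1x - q1x, p1y - q1y);
      double d2 = cross2(q2x - q1x, q2y - q1y, p2x - q1x, p2y - q1y);
      double d3 = cross2(p2x - p1x, p2y - p1y, q1x - p1x, q1y - p1y);
      double d4 = cross2(p2x - p1x, p2y - p1y, q2x - p1x, q2y - p1y);
      if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
          ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps)))
        return false;
      auto on_seg = [eps](double axp, double ayp, double bxp, double byp,
                          double px, double py, double d) {
        if (std::fabs(d) > eps) return false;
        return px >= std::min(axp, bxp) - eps && px <= std::max(axp, bxp) + eps &&
               py >= std::min(ayp, byp) - eps && py <= std::max(ayp, byp) + eps;
      };
      if (on_seg(q1x, q1y, q2x, q2y, p1x, p1y, d1) ||
          on_seg(q1x, q1y, q2x, q2y, p2x, p2y, d2) ||
          on_seg(p1x, p1y, p2x, p2y, q1x, q1y, d3) ||
          on_seg(p1x, p1y, p2x, p2y, q2x, q2y, d4))
        return false;
    }
  }
  return true;
}

// total astral potential of a placement: +sum L^(beta+1)/(beta+1), both poles
// [[Rcpp::export]]
double cpp_placement_potential(NumericMatrix V, double cx, double cy,
                               double angle_deg, double length, double beta,
                               int n_rays) {
  Poly P = make_poly(V);
  std::vector<double> dx, dy;
  make_dirs(n_rays, dx, dy);
  Placement pl = placement_terms(P, cx, cy, angle_deg, length, dx, dy,
                                 beta, int_exponent(beta));
  return pl.ok ? pl.W : R_PosInf;
}

// net force and torque of a single placement (for inspection/tests)
// [[Rcpp::export]]
NumericVector cpp_placement_force(NumericMatrix V, double cx, double cy,
                                  double angle_deg, double length, double beta,
                                  int n_rays) {
  Poly P = make_poly(V);
  std::vector<double> dx, dy;
  make_dirs(n_rays, dx, dy);
  Placement pl = placement_terms(P, cx, cy, angle_deg, length, dx, dy,
                                 beta, int_exponent(beta));
  if (!pl.ok)
    return NumericVector::create(_["Fx"] = NA_REAL, _["Fy"] = NA_REAL,
                                 _["torque"] = NA_REAL, _["potential"] = NA_REAL);
  return NumericVector::create(_["Fx"] = pl.Fx, _["Fy"] = pl.Fy,
                               _["torque"] = pl.torque, _["potential"] = pl.W);
}

// deterministic 8-direction compass search minimizing |F_total|^2 over the center
static Placement balance_center(const Poly& P, double angle_deg, double length,
                                const std::vector<double>& dx,
                                const std::vector<double>& dy,
                                double beta, int ibeta, double& cx, double& cy,
                                double step0, double step_tol) {
  static const double mx[8] = {1, -1, 0, 0, 0.7071067811865476, 0.7071067811865476,
                               -0.7071067811865476, -0.7071067811865476};
  static const double my[8] = {0, 0, 1, -1, 0.7071067811865476, -0.7071067811865476,
                               0.7071067811865476, -0.7071067811865476};
  Placement cur = placement_terms(P, cx, cy, angle_deg, length, dx, dy, beta, ibeta);
  if (!cur.ok) return cur;
  double h = step0;
  int evals = 0;
  while (h > step_tol && evals < 20000) {
    Placement best = cur;
    double bx = cx, by = cy;
    bool moved = false;
    for (int d = 0; d < 8; ++d) {
      double tx = cx + h * mx[d], ty = cy + h * my[d];
      Placement t = placement_terms(P, tx, ty, angle_deg, length, dx, dy, beta, ibeta);
      ++evals;
      if (t.ok && t.fnorm2 < best.fnorm2) { best = t; bx = tx; by = ty; moved = true; }
    }
    if (moved) { cur = best; cx = bx; cy = by; }
    else h *= 0.5;
  }
  return cur;
}

// Orientation scan: for each angle, balance the center (or keep it fixed),
// then record the torque about the spindle center, the astral potential and
// the residual force norm.
// [[Rcpp::export]]
List cpp_force_scan(NumericMatrix V, NumericVector angles_deg, double length,
                    double beta, int n_rays, bool optimize_center,
                    double seed_cx, double seed_cy, double step0,
                    double warm_step, double step_tol) {
  Poly P = make_poly(V);
  std::vector<double> dx, dy;
  make_dirs(n_rays, dx, dy);
  int ibeta = int_exponent(beta);
  int A = angles_deg.size();
  NumericVector tq(A), W(A), cxs(A), cys(A), fn(A);
  LogicalVector ok(A);
  double wx = seed_cx, wy = seed_cy;
  bool warm = false;
  for (int a = 0; a < A; ++a) {
    double ang = angles_deg[a];
    double cx = warm ? wx : seed_cx, cy = warm ? wy : seed_cy;
    Placement pl = placement_terms(P, cx, cy, ang, length, dx, dy, beta, ibeta);
    if (!pl.ok && warm) {
      cx = seed_cx; cy = seed_cy;
      pl = placement_terms(P, cx, cy, ang, length, dx, dy, beta, ibeta);
    }
    if (pl.ok && optimize_center)
      pl = balance_center(P, ang, length, dx, dy, beta, ibeta, cx, cy,
                          warm ? warm_step : step0, step_tol);
    ok[a] = pl.ok;
    tq[a] = pl.ok ? pl.torque : NA_REAL;
    W[a] = pl.ok ? pl.W : NA_REAL;
    fn[a] = pl.ok ? std::sqrt(pl.fnorm2) : NA_REAL;
    cxs[a] = cx;
    cys[a] = cy;
    if (pl.ok) { wx = cx; wy = cy; warm = true; }
  }
  return List::create(_["torque"] = tq, _["potential"] = W, _["cx"] = cxs,
                      _["cy"] = cys, _["force_residual"] = fn, _["feasible"] = ok);
}

// Exhaustive reference scan: for every angle on the fine grid, the lattice
// center minimizing |F_total|^2; torque recorded there.
// [[Rcpp::export]]
List cpp_force_brute(NumericMatrix V, double length, double beta, int n_rays,
                     double dtheta, double grid_step) {
  Poly P = make_poly(V);
  std::vector<double> dx, dy;
  make_dirs(n_rays, dx, dy);
  int ibeta = int_exponent(beta);
  double xmin = P.x[0], xmax = P.x[0], ymin = P.y[0], ymax = P.y[0];
  for (int i = 1; i < P.n; ++i) {
    xmin = std::min(xmin, P.x[i]); xmax = std::max(xmax, P.x[i]);
    ymin = std::min(ymin, P.y[i]); ymax = std::max(ymax, P.y[i]);
  }
  long ix0 = (long)std::ceil(xmin / grid_step), ix1 = (long)std::floor(xmax / grid_step);
  long iy0 = (long)std::ceil(ymin / grid_step), iy1 = (long)std::floor(ymax / grid_step);
  int nA = (int)std::floor(180.0 / dtheta + 1e-9);
  NumericVector angs(nA), tq(nA), W(nA), cxs(nA), cys(nA);
  LogicalVector ok(nA);
  for (int a = 0; a < nA; ++a) {
    if (a % 16 == 0) Rcpp::checkUserInterrupt();
    double ang = a * dtheta;
    angs[a] = ang;
    double bestf = R_PosInf;
    Placement bestp; bestp.ok = false;
    double bx = NA_REAL, by = NA_REAL;
    for (long iy = iy0; iy <= iy1; ++iy) {
      double cy = iy * grid_step;
      for (long ix = ix0; ix <= ix1; ++ix) {
        double cx = ix * grid_step;
        Placement pl = placement_terms(P, cx, cy, ang, length, dx, dy, beta, ibeta);
        if (pl.ok && pl.fnorm2 < bestf) {
          bestf = pl.fnorm2; bestp = pl; bx = cx; by = cy;
        }
      }
    }
    ok[a] = bestp.ok;
    tq[a] = bestp.ok ? bestp.torque : NA_REAL;
    W[a] = bestp.ok ? bestp.W : NA_REAL;
    cxs[a] = bx;
    cys[a] = by;
  }
  return List::create(_["angles"] = angs, _["torque"] = tq, _["potential"] = W,
                      _["cx"] = cxs, _["cy"] = cys, _["feasible"] = ok);
}
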