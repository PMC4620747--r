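// Core enumeration machinery for the near-optimal GDT search.
//
// For every candidate anchor pair (k, l) of model residues, candidate image
// points a^k of b_k are taken from a cubic lattice (anchored at the target
// atom a_k) inside the open ball B(a_k, theta + eps/6), and candidate image
// points a^l of b_l from a geodesic grid on the sphere S(a^k, ||b_k - b_l||)
// restricted to B(a_l, theta + eps/3).  Each pair (a^k, a^l) pins the model
// up to a twist about the axis a^k -> a^l; the twist maximizing the number
// of residues within the cutoff is found exactly by an event sweep over the
// per-residue feasibility arcs.  All thresholds are accumulated in one pass:
// a candidate updates slot i exactly when ||a_k - a^k|| < theta_i + eps/6
// and ||a_l - a^l|| < theta_i + eps/3, with sweep cutoff theta_i + eps.
//
// Exactness-preserving accelerations:
//  * slots whose incumbent has reached n are certified (no transform can
//    beat a full count), shrinking the enumeration radius dynamically;
//  * a candidate image a^k is skipped when the sphere-feasibility bound
//    #{i : | ||a_i - a^k|| - ||b_i - b_k|| | <= cutoff} cannot beat any
//    live incumbent;
//  * a sweep is skipped when the count of non-empty arcs cannot beat the
//    incumbent.
// None of these drop a candidate that could improve an H_i.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// wrap an angle into [0, 2*pi)
static inline double wrap_angle(double x) {
  const double TWO_PI = 2 * M_PI;
  x -= std::floor(x / TWO_PI) * TWO_PI;
  if (x >= TWO_PI) x -= TWO_PI;
  if (x < 0) x += TWO_PI;
  return x;
}

static inline double dist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline void unit_perp(const double* u, double* p1, double* p2) {
  // deterministic basis perpendicular to unit vector u
  double ax = std::fabs(u[0]), ay = std::fabs(u[1]), az = std::fabs(u[2]);
  double e[3] = {0.0, 0.0, 0.0};
  if (ax <= ay && ax <= az) e[0] = 1.0;
  else if (ay <= az) e[1] = 1.0;
  else e[2] = 1.0;
  double d = e[0] * u[0] + e[1] * u[1] + e[2] * u[2];
  p1[0] = e[0] - d * u[0]; p1[1] = e[1] - d * u[1]; p1[2] = e[2] - d * u[2];
  double n = std::sqrt(p1[0] * p1[0] + p1[1] * p1[1] + p1[2] * p1[2]);
  p1[0] /= n; p1[1] /= n; p1[2] /= n;
  p2[0] = u[1] * p1[2] - u[2] * p1[1];
  p2[1] = u[2] * p1[0] - u[0] * p1[2];
  p2[2] = u[0] * p1[1] - u[1] * p1[0];
}

struct LatticePoint { double d2; double x, y, z; };

static std::vector<LatticePoint> lattice_in_ball(const double* c,
                                                 double radius, double side) {
  std::vector<LatticePoint> out;
  if (radius <= 0) return out;
  int N = (int)std::floor(radius / side);
  double r2 = (radius - 1e-12) * (radius - 1e-12);
  for (int i = -N; i <= N; ++i)
    for (int j = -N; j <= N; ++j)
      for (int k = -N; k <= N; ++k) {
        double d2 = (double)(i * i + j * j + k * k) * side * side;
        if (d2 < r2) {
          LatticePoint p;
          p.d2 = d2;
          p.x = c[0] + side * i; p.y = c[1] + side * j; p.z = c[2] + side * k;
          out.push_back(p);
        }
      }
  std::sort(out.begin(), out.end(),
            [](const LatticePoint& a, const LatticePoint& b) {
              return a.d2 < b.d2;
            });
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_translation_grid(NumericVector center, double radius,
                                   double side) {
  if (side <= 0) stop("side must be positive");
  if (radius <= 0) stop("radius must be positive");
  double c[3] = {center[0], center[1], center[2]};
  std::vector<LatticePoint> pts = lattice_in_ball(c, radius, side);
  NumericMatrix out(pts.size(), 3);
  for (size_t i = 0; i < pts.size(); ++i) {
    out(i, 0) = pts[i].x; out(i, 1) = pts[i].y; out(i, 2) = pts[i].z;
  }
  return out;
}

// Geodesic grid on the sphere S(sc, r): latitude bands at angular step
// spacing/r measured from the direction sc -> bc, each band sampled in
// longitude at arc step <= spacing; restricted to points within
// ball_radius + spacing of bc (one-spacing margin).
// [[Rcpp::export]]
NumericMatrix cpp_cap_grid(NumericVector sphere_center, double sphere_radius,
                           NumericVector ball_center, double ball_radius,
                           double spacing) {
  if (sphere_radius <= 0) stop("sphere_radius must be positive");
  if (spacing <= 0) stop("spacing must be positive");
  double sc[3] = {sphere_center[0], sphere_center[1], sphere_center[2]};
  double bc[3] = {ball_center[0], ball_center[1], ball_center[2]};
  double r = sphere_radius;
  double D = dist3(sc, bc);
  double keep = ball_radius + spacing;   // margin
  double uw[3];
  double omega_max;
  if (D < 1e-12) {
    // ball concentric with the sphere
    if (r > ball_radius + spacing) return NumericMatrix(0, 3);
    uw[0] = 0; uw[1] = 0; uw[2] = 1;
    omega_max = M_PI;
  } else {
    uw[0] = (bc[0] - sc[0]) / D; uw[1] = (bc[1] - sc[1]) / D;
    uw[2] = (bc[2] - sc[2]) / D;
    double K = (r * r + D * D - ball_radius * ball_radius) / (2 * r * D);
    if (K > 1.0) {
      // sphere does not reach the ball; still allow the margin
      double Km = (r * r + D * D - keep * keep) / (2 * r * D);
      if (Km > 1.0) return NumericMatrix(0, 3);
      omega_max = 0.0;
    } else {
      omega_max = (K <= -1.0) ? M_PI : std::acos(K);
    }
  }
  double p1[3], p2[3];
  unit_perp(uw, p1, p2);
  double domega = spacing / r;
  int nb = (int)std::ceil(omega_max / domega) + 1;   // margin band
  std::vector<double> xs, ys, zs;
  for (int j = 0; j <= nb; ++j) {
    double om = j * domega;
    bool last = false;
    if (om >= M_PI) { om = M_PI; last = true; }
    double rs = r * std::sin(om), zc = r * std::cos(om);
    int nlon = std::max(1, (int)std::ceil(2 * M_PI * rs / spacing));
    for (int t = 0; t < nlon; ++t) {
      double lam = 2 * M_PI * t / nlon;
      double p[3];
      for (int d = 0; d < 3; ++d)
        p[d] = sc[d] + zc * uw[d] +
               rs * (std::cos(lam) * p1[d] + std::sin(lam) * p2[d]);
      if (dist3(p, bc) <= keep) {
        xs.push_back(p[0]); ys.push_back(p[1]); zs.push_back(p[2]);
      }
    }
    if (last) break;
  }
  NumericMatrix out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = zs[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_gdt_search(NumericMatrix A, NumericMatrix B, double eps,
                    NumericVector thetas, IntegerVector H0,
                    IntegerMatrix anchors, double side, double spacing,
                    double tol, double max_candidates) {
  const int n = A.nrow();
  const int m = thetas.size();
  if (B.nrow() != n) stop("target/model length mismatch");
  for (int i = 1; i < m; ++i)
    if (thetas[i] <= thetas[i - 1]) stop("thetas must be ascending");

  std::vector<int> H(H0.begin(), H0.end());
  std::vector<int> wit_k(m, -1), wit_l(m, -1);
  std::vector<double> wit_ak(3 * m, NA_REAL), wit_al(3 * m, NA_REAL);

  int itop = m - 1;
  while (itop >= 0 && H[itop] >= n) --itop;

  double n_candidates = 0.0, n_sweeps = 0.0;

  // scratch
  std::vector<double> rdist(n), alpha(n), rho(n), rho2(n), psi(n);
  std::vector<double> Acoef(n), Bcoef(n), minc2(n), maxc2(n), centre(n);
  std::vector<double> gk(n);
  std::vector<std::pair<double, int> > events;
  events.reserve(2 * n);

  std::vector<double> Arow(3 * n), Brow(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      Arow[3 * i + d] = A(i, d);
      Brow[3 * i + d] = B(i, d);
    }

  for (int ap = 0; ap < anchors.nrow() && itop >= 0; ++ap) {
    Rcpp::checkUserInterrupt();
    int k = anchors(ap, 0) - 1, l = anchors(ap, 1) - 1;
    if (k < 0 || l < 0 || k >= n || l >= n || k == l) stop("bad anchor pair");
    const double* bk = &Brow[3 * k];
    const double* bl = &Brow[3 * l];
    const double* akt = &Arow[3 * k];   // target atom a_k
    const double* alt = &Arow[3 * l];
    double r = dist3(bk, bl);
    if (r < 1e-9) continue;             // degenerate anchor, skipped
    // model-frame geometry (rigid-invariant)
    double v[3] = {(bl[0] - bk[0]) / r, (bl[1] - bk[1]) / r,
                   (bl[2] - bk[2]) / r};
    double m1[3], m2[3];
    unit_perp(v, m1, m2);
    for (int i = 0; i < n; ++i) {
      const double* bi = &Brow[3 * i];
      double d0 = bi[0] - bk[0], d1 = bi[1] - bk[1], d2v = bi[2] - bk[2];
      rdist[i] = std::sqrt(d0 * d0 + d1 * d1 + d2v * d2v);
      double al_ = d0 * v[0] + d1 * v[1] + d2v * v[2];
      alpha[i] = al_;
      double e0 = d0 - al_ * v[0], e1 = d1 - al_ * v[1], e2 = d2v - al_ * v[2];
      double rr = std::sqrt(e0 * e0 + e1 * e1 + e2 * e2);
      rho[i] = rr; rho2[i] = rr * rr;
      psi[i] = (rr > 1e-12)
                 ? std::atan2(e0 * m2[0] + e1 * m2[1] + e2 * m2[2],
                              e0 * m1[0] + e1 * m1[1] + e2 * m1[2])
                 : 0.0;
    }

    double Rt = thetas[itop] + eps / 6.0;
    std::vector<LatticePoint> grid = lattice_in_ball(akt, Rt, side);

    for (size_t gi = 0; gi < grid.size() && itop >= 0; ++gi) {
      double ak[3] = {grid[gi].x, grid[gi].y, grid[gi].z};
      double dk = std::sqrt(grid[gi].d2);
      if (dk >= thetas[itop] + eps / 6.0 + tol) break;  // sorted ascending
      // sphere-feasibility bound per live slot
      for (int i = 0; i < n; ++i)
        gk[i] = std::fabs(dist3(&Arow[3 * i], ak) - rdist[i]);
      bool any_live = false;
      std::vector<bool> live(m, false);
      for (int s = 0; s < m; ++s) {
        if (H[s] >= n) continue;
        if (dk >= thetas[s] + eps / 6.0 + tol) continue;
        double c = thetas[s] + eps + tol;
        int ub = 0;
        for (int i = 0; i < n; ++i) if (gk[i] <= c) ++ub;
        if (ub > H[s]) { live[s] = true; any_live = true; }
      }
      if (!any_live) continue;

      // geodesic cap grid on S(ak, r) toward a_l, enumerated inline
      double D = dist3(ak, alt);
      double Rb = thetas[itop] + eps / 3.0;
      double uw[3], omega_max;
      if (D < 1e-12) {
        if (r >= Rb + tol) continue;
        uw[0] = 0; uw[1] = 0; uw[2] = 1;
        omega_max = M_PI;
      } else {
        uw[0] = (alt[0] - ak[0]) / D; uw[1] = (alt[1] - ak[1]) / D;
        uw[2] = (alt[2] - ak[2]) / D;
        double K = (r * r + D * D - Rb * Rb) / (2 * r * D);
        if (K > 1.0) continue;          // sphere misses the ball
        omega_max = (K <= -1.0) ? M_PI : std::acos(K);
      }
      double p1[3], p2[3];
      unit_perp(uw, p1, p2);
      double domega = spacing / r;
      int nb = (int)std::ceil(omega_max / domega) + 1;

      for (int jb = 0; jb <= nb && itop >= 0; ++jb) {
        double om = jb * domega;
        bool lastband = false;
        if (om >= M_PI) { om = M_PI; lastband = true; }
        double rs = r * std::sin(om), zc = r * std::cos(om);
        int nlon = std::max(1, (int)std::ceil(2 * M_PI * rs / spacing));
        for (int tt = 0; tt < nlon; ++tt) {
          double lam = 2 * M_PI * tt / nlon;
          double al[3];
          for (int d = 0; d < 3; ++d)
            al[d] = ak[d] + zc * uw[d] +
                    rs * (std::cos(lam) * p1[d] + std::sin(lam) * p2[d]);
          double dl = dist3(al, alt);
          if (dl >= thetas[itop] + eps / 3.0 + tol) continue;
          n_candidates += 1.0;
          if (n_candidates > max_candidates)
            stop("candidate budget exceeded; coarsen the search "
                 "(larger epsilon or thinning factors)");

          // candidate axis
          double u2[3] = {(al[0] - ak[0]) / r, (al[1] - ak[1]) / r,
                          (al[2] - ak[2]) / r};
          double f1[3], f2[3];
          unit_perp(u2, f1, f2);
          bool geom_done = false;

          for (int s = 0; s < m; ++s) {
            if (H[s] >= n || !live[s]) continue;
            if (dk >= thetas[s] + eps / 6.0 + tol) continue;
            if (dl >= thetas[s] + eps / 3.0 + tol) continue;
            double c = thetas[s] + eps;
            double c2 = (c + tol) * (c + tol);
            if (!geom_done) {
              for (int i = 0; i < n; ++i) {
                double cx0 = ak[0] + alpha[i] * u2[0];
                double cx1 = ak[1] + alpha[i] * u2[1];
                double cx2 = ak[2] + alpha[i] * u2[2];
                double w0 = Arow[3 * i] - cx0, w1 = Arow[3 * i + 1] - cx1,
                       w2 = Arow[3 * i + 2] - cx2;
                double wpar = w0 * u2[0] + w1 * u2[1] + w2 * u2[2];
                double wp0 = w0 - wpar * u2[0], wp1 = w1 - wpar * u2[1],
                       wp2 = w2 - wpar * u2[2];
                double q2 = wp0 * wp0 + wp1 * wp1 + wp2 * wp2;
                double q = std::sqrt(q2);
                Acoef[i] = wpar * wpar + q2 + rho2[i];
                Bcoef[i] = 2.0 * rho[i] * q;
                minc2[i] = Acoef[i] - Bcoef[i];
                maxc2[i] = Acoef[i] + Bcoef[i];
                centre[i] = (Bcoef[i] > 1e-15)
                              ? std::atan2(wp0 * f2[0] + wp1 * f2[1] +
                                           wp2 * f2[2],
                                           wp0 * f1[0] + wp1 * f1[1] +
                                           wp2 * f1[2]) - psi[i]
                              : 0.0;
              }
              geom_done = true;
            }
            int ub = 0;
            for (int i = 0; i < n; ++i) if (minc2[i] <= c2) ++ub;
            if (ub <= H[s]) continue;

            // event sweep over proper arcs
            n_sweeps += 1.0;
            int base = 0;
            events.clear();
            int init = 0;
            for (int i = 0; i < n; ++i) {
              if (minc2[i] > c2) continue;
              if (maxc2[i] <= c2 || Bcoef[i] <= 1e-15) { ++base; continue; }
              double kap = (Acoef[i] - c2) / Bcoef[i];
              if (kap < -1.0) kap = -1.0;
              if (kap > 1.0) kap = 1.0;
              double hw = std::acos(kap);
              double st = wrap_angle(centre[i] - hw);
              double en = wrap_angle(centre[i] + hw);
              if (st > en) ++init;              // arc wraps through 0
              events.push_back(std::make_pair(st, 1));
              events.push_back(std::make_pair(en, -1));
            }
            int best = init;
            if (!events.empty()) {
              std::sort(events.begin(), events.end(),
                        [](const std::pair<double, int>& a,
                           const std::pair<double, int>& b) {
                          if (a.first != b.first) return a.first < b.first;
                          return a.second > b.second;  // entries first
                        });
              int run = init;
              for (size_t ev = 0; ev < events.size(); ++ev) {
                run += events[ev].second;
                if (run > best) best = run;
              }
            }
            int cnt = base + best;
            if (cnt > H[s]) {
              // update slot s and certify every later slot if full
              int hi = (cnt >= n) ? (m - 1) : s;
              for (int s2 = s; s2 <= hi; ++s2) {
                if (cnt > H[s2]) {
                  H[s2] = cnt;
                  wit_k[s2] = k + 1; wit_l[s2] = l + 1;
                  for (int d = 0; d < 3; ++d) {
                    wit_ak[3 * s2 + d] = ak[d];
                    wit_al[3 * s2 + d] = al[d];
                  }
                }
              }
              if (cnt >= n) {
                while (itop >= 0 && H[itop] >= n) --itop;
                if (itop < s) break;
              }
            }
          }
          if (itop < 0) break;
        }
        if (lastband) break;
      }
    }
  }

  NumericMatrix wak(m, 3), wal(m, 3);
  IntegerVector wk(m), wl(m);
  for (int s = 0; s < m; ++s) {
    wk[s] = (wit_k[s] > 0) ? wit_k[s] : NA_INTEGER;
    wl[s] = (wit_l[s] > 0) ? wit_l[s] : NA_INTEGER;
    for (int d = 0; d < 3; ++d) {
      wak(s, d) = wit_ak[3 * s + d];
      wal(s, d) = wit_al[3 * s + d];
    }
  }
  return List::create(_["H"] = IntegerVector(H.begin(), H.end()),
                      _["wit_k"] = wk, _["wit_l"] = wl,
                      _["wit_ak"] = wak, _["wit_al"] = wal,
                      _["n_candidates"] = n_candidates,
                      _["n_sweeps"] = n_sweeps);
}
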