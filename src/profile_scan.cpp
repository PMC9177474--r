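#include <Rcpp.h>
#include <cmath>
#include <cfloat>

// Profiled least squares for the four-parameter logistic.
//
// For fixed (inflection c, steepness s) the prediction is linear in the
// asymptotes: pred = a(1 - sig) + b sig with 0 <= a <= b <= 1. The
// constrained minimiser over (a, b) is exact (active-set enumeration), so
// the outer problem is a smooth 2-d minimisation over (c, log s), handled
// by a lattice scan plus deterministic compass search. This runs for every
// point of the (k, h) shift grid, hence the compiled implementation.

namespace {

struct Bounds { double a, b, ss; };

inline double sigm(double z) {
  if (z >= 0) {
    double e = std::exp(-z);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

// exact box/order-constrained 2-parameter linear LS given the sigmoids
Bounds best_bounds(const double* sig, const double* p, int m) {
  double s11 = 0, s12 = 0, s22 = 0, y1 = 0, y2 = 0, pp = 0;
  for (int i = 0; i < m; ++i) {
    double x2 = sig[i], x1 = 1.0 - x2;
    s11 += x1 * x1; s12 += x1 * x2; s22 += x2 * x2;
    y1 += x1 * p[i]; y2 += x2 * p[i]; pp += p[i] * p[i];
  }
  auto ss_of = [&](double a, double b) {
    return a * a * s11 + b * b * s22 + 2 * a * b * s12
         - 2 * a * y1 - 2 * b * y2 + pp;
  };
  Bounds best; best.a = 0; best.b = 0; best.ss = DBL_MAX;
  double det = s11 * s22 - s12 * s12;
  if (det > DBL_EPSILON * std::max(s11 * s22, 1.0)) {
    double a = (y1 * s22 - y2 * s12) / det;
    double b = (s11 * y2 - s12 * y1) / det;
    if (a >= 0 && b <= 1 && a <= b) { best.a = a; best.b = b; best.ss = ss_of(a, b); }
  }
  double b0 = s22 > 0 ? y2 / s22 : 0.0;           // edge a = 0
  b0 = std::min(std::max(b0, 0.0), 1.0);
  double ss0 = ss_of(0.0, b0);
  if (ss0 < best.ss) { best.a = 0; best.b = b0; best.ss = ss0; }
  double a1 = s11 > 0 ? (y1 - s12) / s11 : 0.0;   // edge b = 1
  a1 = std::min(std::max(a1, 0.0), 1.0);
  double ss1 = ss_of(a1, 1.0);
  if (ss1 < best.ss) { best.a = a1; best.b = 1; best.ss = ss1; }
  double mp = 0;                                   // edge a = b (flat line)
  for (int i = 0; i < m; ++i) mp += p[i];
  mp = std::min(std::max(mp / m, 0.0), 1.0);
  double ssf = ss_of(mp, mp);
  if (ssf < best.ss) { best.a = mp; best.b = mp; best.ss = ssf; }
  if (best.ss < 0) best.ss = 0;  // round-off guard
  return best;
}

double profile_ss(const double* phi, const double* p, int m,
                  double c, double t, double* sigbuf) {
  double s = std::exp(t);
  for (int i = 0; i < m; ++i) sigbuf[i] = sigm(s * (phi[i] - c));
  return best_bounds(sigbuf, p, m).ss;
}

struct Fit { double ss, c, t; };

// deterministic compass search on (c, t = log steepness)
Fit compass(const double* phi, const double* p, int m,
            double c0, double t0, double dc0, double dt0, double* sigbuf) {
  Fit cur; cur.c = c0; cur.t = t0;
  cur.ss = profile_ss(phi, p, m, c0, t0, sigbuf);
  double dc = dc0, dt = dt0;
  const double tol_c = 1e-9 * (1.0 + std::fabs(dc0) * 20.0);
  for (int it = 0; it < 400; ++it) {
    bool moved = false;
    const double moves[4][2] = {{dc, 0}, {-dc, 0}, {0, dt}, {0, -dt}};
    for (int k = 0; k < 4; ++k) {
      double cc = cur.c + moves[k][0];
      double tt = cur.t + moves[k][1];
      if (tt < -12 || tt > 8) continue;  // steepness in [6e-6, 3e3]
      double ss = profile_ss(phi, p, m, cc, tt, sigbuf);
      if (ss < cur.ss) { cur.ss = ss; cur.c = cc; cur.t = tt; moved = true; }
    }
    if (!moved) {
      dc *= 0.5; dt *= 0.5;
      if (dc < tol_c && dt < 1e-9) break;
    }
  }
  return cur;
}

} // namespace

// [[Rcpp::export(name = ".profile_scan_cpp")]]
Rcpp::NumericMatrix profile_scan_cpp(Rcpp::NumericMatrix phi_mat,
                                     Rcpp::NumericVector p,
                                     int n_c = 21,
                                     int n_starts = 3) {
  const int G = phi_mat.nrow();
  const int m = phi_mat.ncol();
  if (p.size() != m) Rcpp::stop("phi/p dimension mismatch");
  Rcpp::NumericMatrix out(G, 5);  // ss, c, s, lower, upper
  std::vector<double> phi(m), sig(m), pv(p.begin(), p.end());
  // steepness lattice, log-spaced in [0.02, 5]
  const int n_s = 13;
  std::vector<double> tgrid(n_s);
  for (int j = 0; j < n_s; ++j)
    tgrid[j] = std::log(0.02) + j * (std::log(5.0) - std::log(0.02)) / (n_s - 1);

  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < m; ++i) phi[i] = phi_mat(g, i);
    double lo = phi[0], hi = phi[0];
    for (int i = 1; i < m; ++i) { lo = std::min(lo, phi[i]); hi = std::max(hi, phi[i]); }
    double range = hi - lo;
    if (range <= 0) range = 1.0;
    // lattice scan, keeping the n_starts best (c, t) cells
    std::vector<Fit> best(n_starts);
    for (int q = 0; q < n_starts; ++q) best[q].ss = DBL_MAX;
    for (int ic = 0; ic < n_c; ++ic) {
      double c = lo + ic * range / (n_c - 1);
      for (int is = 0; is < n_s; ++is) {
        double ss = profile_ss(phi.data(), pv.data(), m, c, tgrid[is], sig.data());
        int worst = 0;
        for (int q = 1; q < n_starts; ++q)
          if (best[q].ss > best[worst].ss) worst = q;
        if (ss < best[worst].ss) {
          best[worst].ss = ss; best[worst].c = c; best[worst].t = tgrid[is];
        }
      }
    }
    double dc0 = range / (n_c - 1);
    double dt0 = tgrid[1] - tgrid[0];
    Fit win; win.ss = DBL_MAX; win.c = lo; win.t = 0;
    for (int q = 0; q < n_starts; ++q) {
      if (best[q].ss == DBL_MAX) continue;
      Fit f = compass(phi.data(), pv.data(), m, best[q].c, best[q].t,
                      dc0, dt0, sig.data());
      if (f.ss < win.ss) win = f;
    }
    double s = std::exp(win.t);
    for (int i = 0; i < m; ++i) sig[i] = sigm(s * (phi[i] - win.c));
    Bounds bb = best_bounds(sig.data(), pv.data(), m);
    out(g, 0) = bb.ss; out(g, 1) = win.c; out(g, 2) = s;
    out(g, 3) = bb.a; out(g, 4) = bb.b;
  }
  return out;
}
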