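// Coarse-grained restrained backbone energy and analytic gradient.
//
// Atom layout: 5 atoms per residue in the order N, CA, C, O, CB; coords is
// a flat vector of length 15 * L (xyz per atom). Restraint potentials are
// natural cubic splines through geometry-bin centers (negative log
// probability ratios), evaluated with linear extrapolation beyond the
// terminal knots; periodic maps are padded on the R side so that the
// spline covers the full wrapped domain. Physical terms: soft-sphere
// steric repulsion, harmonic ideal bond/angle/improper deviations, and an
// omega (peptide-bond torsion) planarity penalty.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double RAD2DEG = 57.29577951308232;

// ---- small vector helpers -------------------------------------------------

static inline void vsub(const double* a, const double* b, double* o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// Dihedral angle (radians, (-pi, pi]) for atoms a-b-c-d with optional
// gradient (d angle / d coordinate, radians). Returns NaN if degenerate.
static double dihedral_val_grad(const double* a, const double* b,
                                const double* c, const double* d,
                                double* ga, double* gb, double* gc,
                                double* gd, bool want_grad) {
  double b1[3], b2[3], b3[3], n1[3], n2[3];
  vsub(b, a, b1); vsub(c, b, b2); vsub(d, c, b3);
  vcross(b1, b2, n1); vcross(b2, b3, n2);
  double ln1 = vnorm(n1), ln2 = vnorm(n2), lb2 = vnorm(b2);
  if (ln1 < 1e-7 || ln2 < 1e-7 || lb2 < 1e-12) return NA_REAL;
  double m1[3];
  double ub2[3] = { b2[0] / lb2, b2[1] / lb2, b2[2] / lb2 };
  vcross(n1, ub2, m1);
  double x = vdot(n1, n2), y = -vdot(m1, n2);
  double phi = std::atan2(y, x);
  if (want_grad) {
    // analytic gradient (Blondel-Karplus style, matching this atan2
    // convention; verified against finite differences)
    double f1 = -lb2 / (ln1 * ln1);
    double f4 =  lb2 / (ln2 * ln2);
    double da[3] = { f1 * n1[0], f1 * n1[1], f1 * n1[2] };
    double dd[3] = { f4 * n2[0], f4 * n2[1], f4 * n2[2] };
    double c12 = vdot(b1, b2) / (lb2 * lb2);
    double c32 = vdot(b3, b2) / (lb2 * lb2);
    for (int k = 0; k < 3; ++k) {
      ga[k] = da[k];
      gb[k] = -(1.0 + c12) * da[k] + c32 * dd[k];
      gc[k] = c12 * da[k] - (1.0 + c32) * dd[k];
      gd[k] = dd[k];
    }
  }
  return phi;
}

// Planar angle (radians, [0, pi]) at b for atoms a-b-c with gradient.
static double angle_val_grad(const double* a, const double* b,
                             const double* c, double* ga, double* gb,
                             double* gc, bool want_grad) {
  double u[3], v[3];
  vsub(a, b, u); vsub(c, b, v);
  double lu = vnorm(u), lv = vnorm(v);
  if (lu < 1e-7 || lv < 1e-7) return NA_REAL;
  double cs = vdot(u, v) / (lu * lv);
  if (cs > 1.0) cs = 1.0;
  if (cs < -1.0) cs = -1.0;
  double th = std::acos(cs);
  if (want_grad) {
    double sn = std::sqrt(1.0 - cs * cs);
    if (sn < 1e-8) sn = 1e-8;
    for (int k = 0; k < 3; ++k) {
      double du = (v[k] / (lu * lv)) - cs * u[k] / (lu * lu);
      double dv = (u[k] / (lu * lv)) - cs * v[k] / (lv * lv);
      ga[k] = -du / sn;
      gc[k] = -dv / sn;
      gb[k] = -(ga[k] + gc[k]);
    }
  }
  return th;
}

// ---- natural cubic splines ------------------------------------------------

// Second derivatives of a natural cubic spline per row of Y.
// [[Rcpp::export]]
NumericMatrix cpp_spline_y2(NumericVector x, NumericMatrix Y) {
  int n = x.size(), m = Y.nrow();
  if (Y.ncol() != n) stop("Y must have one column per knot");
  NumericMatrix Y2(m, n);
  std::vector<double> u(n);
  for (int r = 0; r < m; ++r) {
    Y2(r, 0) = 0.0; u[0] = 0.0;
    for (int i = 1; i < n - 1; ++i) {
      double sig = (x[i] - x[i - 1]) / (x[i + 1] - x[i - 1]);
      double p = sig * Y2(r, i - 1) + 2.0;
      Y2(r, i) = (sig - 1.0) / p;
      double uu = (Y(r, i + 1) - Y(r, i)) / (x[i + 1] - x[i]) -
                  (Y(r, i) - Y(r, i - 1)) / (x[i] - x[i - 1]);
      u[i] = (6.0 * uu / (x[i + 1] - x[i - 1]) - sig * u[i - 1]) / p;
    }
    Y2(r, n - 1) = 0.0;
    for (int i = n - 2; i >= 0; --i)
      Y2(r, i) = Y2(r, i) * Y2(r, i + 1) + u[i];
  }
  return Y2;
}

// Evaluate spline row r at t; returns value, sets *deriv. Linear
// extrapolation beyond the terminal knots.
static double spline_eval(const NumericVector& x, const NumericMatrix& Y,
                          const NumericMatrix& Y2, int r, double t,
                          double* deriv) {
  int n = x.size();
  double h0 = x[1] - x[0];
  if (t <= x[0]) {
    double d = (Y(r, 1) - Y(r, 0)) / h0 - h0 / 6.0 * (2.0 * Y2(r, 0) + Y2(r, 1));
    *deriv = d;
    return Y(r, 0) + d * (t - x[0]);
  }
  if (t >= x[n - 1]) {
    double h = x[n - 1] - x[n - 2];
    double d = (Y(r, n - 1) - Y(r, n - 2)) / h +
               h / 6.0 * (Y2(r, n - 2) + 2.0 * Y2(r, n - 1));
    *deriv = d;
    return Y(r, n - 1) + d * (t - x[n - 1]);
  }
  int k = (int)std::floor((t - x[0]) / h0);
  if (k > n - 2) k = n - 2;
  if (k < 0) k = 0;
  double h = x[k + 1] - x[k];
  double A = (x[k + 1] - t) / h, B = 1.0 - A;
  double val = A * Y(r, k) + B * Y(r, k + 1) +
               ((A * A * A - A) * Y2(r, k) + (B * B * B - B) * Y2(r, k + 1)) *
                 h * h / 6.0;
  *deriv = (Y(r, k + 1) - Y(r, k)) / h +
           h / 6.0 * (-(3.0 * A * A - 1.0) * Y2(r, k) +
                      (3.0 * B * B - 1.0) * Y2(r, k + 1));
  return val;
}

// ---- energy ---------------------------------------------------------------

struct Grad {
  std::vector<double>* g;
  bool want;
  void add(int atom, const double* v, double w) {
    if (!want) return;
    (*g)[3 * atom] += w * v[0];
    (*g)[3 * atom + 1] += w * v[1];
    (*g)[3 * atom + 2] += w * v[2];
  }
};

static inline const double* at(const NumericVector& c, int res, int k) {
  return &c[3 * (5 * res + k)];
}
static inline int ai(int res, int k) { return 5 * res + k; }

static double wrap_pi(double d) {
  while (d > M_PI) d -= 2.0 * M_PI;
  while (d <= -M_PI) d += 2.0 * M_PI;
  return d;
}

// [[Rcpp::export]]
List cpp_energy(NumericVector coords, int L, List pot, List par,
                bool want_grad = false) {
  if (coords.size() != 15 * L) stop("coords has wrong length");
  std::vector<double> grad(want_grad ? coords.size() : 0, 0.0);
  Grad G; G.g = &grad; G.want = want_grad;

  const double w_pair  = as<double>(par["w_pair"]);
  const double w_dih   = as<double>(par["w_dih"]);
  const double w_ang   = as<double>(par["w_ang"]);
  const double w_ster  = as<double>(par["w_steric"]);
  const double w_breg  = as<double>(par["w_breg"]);
  const double w_omg   = as<double>(par["w_omegator"]);
  const double kbond   = as<double>(par["kbond"]);
  const double kang    = as<double>(par["kang"]);
  const double kimpr   = as<double>(par["kimpr"]);
  const double komega  = as<double>(par["komega"]);
  const double krep    = as<double>(par["krep"]);
  const double rmin    = as<double>(par["rep_rmin"]);
  List ig = par["ideal"];
  const double t_cb    = as<double>(par["t_cb"]) / RAD2DEG;    // CB improper
  const double a_ncacb = as<double>(par["a_NCACB"]) / RAD2DEG;
  const double a_ccacb = as<double>(par["a_CCACB"]) / RAD2DEG;

  double e_dist = 0, e_dih = 0, e_ang = 0, e_ster = 0, e_breg = 0, e_omg = 0;
  double ga[3], gb[3], gc[3], gd[3];

  // -- distance restraints (CB_i - CB_j) --
  if (pot.containsElementNamed("dist") && !Rf_isNull(pot["dist"])) {
    List P = pot["dist"];
    IntegerMatrix pr = P["pairs"];
    NumericMatrix Y = P["y"], Y2 = P["y2"];
    NumericVector x = P["x"];
    for (int r = 0; r < pr.nrow(); ++r) {
      int i = pr(r, 0) - 1, j = pr(r, 1) - 1;
      const double* pi_ = at(coords, i, 4);
      const double* pj = at(coords, j, 4);
      double dv[3]; vsub(pi_, pj, dv);
      double d = vnorm(dv);
      if (d < 1e-8) continue;
      if (d >= x[x.size() - 1]) continue;  // zero beyond the no-contact edge
      double der;
      e_dist += spline_eval(x, Y, Y2, r, d, &der);
      double f = der / d;
      double gi[3] = { f * dv[0], f * dv[1], f * dv[2] };
      double gj[3] = { -gi[0], -gi[1], -gi[2] };
      G.add(ai(i, 4), gi, w_pair);
      G.add(ai(j, 4), gj, w_pair);
    }
  }

  // -- dihedral restraints (omega: CAi-CBi-CBj-CAj; theta: Ni-CAi-CBi-CBj) --
  const char* dihnames[2] = { "omega", "theta" };
  for (int cls = 0; cls < 2; ++cls) {
    if (!pot.containsElementNamed(dihnames[cls]) ||
        Rf_isNull(pot[dihnames[cls]])) continue;
    List P = pot[dihnames[cls]];
    IntegerMatrix pr = P["pairs"];
    NumericMatrix Y = P["y"], Y2 = P["y2"];
    NumericVector x = P["x"];
    for (int r = 0; r < pr.nrow(); ++r) {
      int i = pr(r, 0) - 1, j = pr(r, 1) - 1;
      int a1, a2, a3, a4;
      if (cls == 0) { a1 = ai(i, 1); a2 = ai(i, 4); a3 = ai(j, 4); a4 = ai(j, 1); }
      else          { a1 = ai(i, 0); a2 = ai(i, 1); a3 = ai(i, 4); a4 = ai(j, 4); }
      double v = dihedral_val_grad(&coords[3 * a1], &coords[3 * a2],
                                   &coords[3 * a3], &coords[3 * a4],
                                   ga, gb, gc, gd, want_grad);
      if (ISNAN(v)) continue;
      double der;
      e_dih += spline_eval(x, Y, Y2, r, v * RAD2DEG, &der);
      double w = w_dih * der * RAD2DEG;
      G.add(a1, ga, w); G.add(a2, gb, w); G.add(a3, gc, w); G.add(a4, gd, w);
    }
  }

  // -- angle restraints (phi: CAi-CBi-CBj) --
  if (pot.containsElementNamed("phi") && !Rf_isNull(pot["phi"])) {
    List P = pot["phi"];
    IntegerMatrix pr = P["pairs"];
    NumericMatrix Y = P["y"], Y2 = P["y2"];
    NumericVector x = P["x"];
    for (int r = 0; r < pr.nrow(); ++r) {
      int i = pr(r, 0) - 1, j = pr(r, 1) - 1;
      int a1 = ai(i, 1), a2 = ai(i, 4), a3 = ai(j, 4);
      double v = angle_val_grad(&coords[3 * a1], &coords[3 * a2],
                                &coords[3 * a3], ga, gb, gc, want_grad);
      if (ISNAN(v)) continue;
      double der;
      e_ang += spline_eval(x, Y, Y2, r, v * RAD2DEG, &der);
      double w = w_ang * der * RAD2DEG;
      G.add(a1, ga, w); G.add(a2, gb, w); G.add(a3, gc, w);
    }
  }

  // -- steric soft-sphere repulsion, residues separated by >= 2 --
  for (int i = 0; i < L; ++i) {
    for (int j = i + 2; j < L; ++j) {
      for (int k = 0; k < 5; ++k) {
        for (int l = 0; l < 5; ++l) {
          const double* p = at(coords, i, k);
          const double* q = at(coords, j, l);
          double dv[3]; vsub(p, q, dv);
          if (std::fabs(dv[0]) > rmin || std::fabs(dv[1]) > rmin ||
              std::fabs(dv[2]) > rmin) continue;
          double d = vnorm(dv);
          if (d >= rmin || d < 1e-8) continue;
          double gap = rmin - d;
          e_ster += krep * gap * gap;
          double f = -2.0 * krep * gap / d;
          double gi[3] = { f * dv[0], f * dv[1], f * dv[2] };
          double gj[3] = { -gi[0], -gi[1], -gi[2] };
          G.add(ai(i, k), gi, w_ster);
          G.add(ai(j, l), gj, w_ster);
        }
      }
    }
  }

  // -- bonded regularity: bonds --
  auto bond_term = [&](int A, int B, double b0) {
    double dv[3]; vsub(&coords[3 * A], &coords[3 * B], dv);
    double d = vnorm(dv);
    if (d < 1e-8) return;
    double dev = d - b0;
    e_breg += kbond * dev * dev;
    double f = 2.0 * kbond * dev / d;
    double gi[3] = { f * dv[0], f * dv[1], f * dv[2] };
    double gj[3] = { -gi[0], -gi[1], -gi[2] };
    G.add(A, gi, w_breg); G.add(B, gj, w_breg);
  };
  auto angle_term = [&](int A, int B, int C, double a0, double k) {
    double v = angle_val_grad(&coords[3 * A], &coords[3 * B], &coords[3 * C],
                              ga, gb, gc, want_grad);
    if (ISNAN(v)) return;
    double dev = v - a0;
    e_breg += k * dev * dev;
    double w = w_breg * 2.0 * k * dev;
    G.add(A, ga, w); G.add(B, gb, w); G.add(C, gc, w);
  };
  auto improper_term = [&](int A, int B, int C, int D, double t0) {
    double v = dihedral_val_grad(&coords[3 * A], &coords[3 * B],
                                 &coords[3 * C], &coords[3 * D],
                                 ga, gb, gc, gd, want_grad);
    if (ISNAN(v)) return;
    double dev = wrap_pi(v - t0);
    e_breg += kimpr * dev * dev;
    double w = w_breg * 2.0 * kimpr * dev;
    G.add(A, ga, w); G.add(B, gb, w); G.add(C, gc, w); G.add(D, gd, w);
  };

  const double a_NCAC = as<double>(ig["a_NCAC"]) / RAD2DEG;
  const double a_CACN = as<double>(ig["a_CACN"]) / RAD2DEG;
  const double a_CNCA = as<double>(ig["a_CNCA"]) / RAD2DEG;
  const double a_CACO = as<double>(ig["a_CACO"]) / RAD2DEG;
  const double a_OCN  = as<double>(ig["a_OCN"])  / RAD2DEG;
  const double b_NCA  = as<double>(ig["b_NCA"]);
  const double b_CAC  = as<double>(ig["b_CAC"]);
  const double b_CN   = as<double>(ig["b_CN"]);
  const double b_CO   = as<double>(ig["b_CO"]);
  const double b_CACB = as<double>(ig["b_CACB"]);

  for (int i = 0; i < L; ++i) {
    bond_term(ai(i, 0), ai(i, 1), b_NCA);
    bond_term(ai(i, 1), ai(i, 2), b_CAC);
    bond_term(ai(i, 2), ai(i, 3), b_CO);
    bond_term(ai(i, 1), ai(i, 4), b_CACB);
    angle_term(ai(i, 0), ai(i, 1), ai(i, 2), a_NCAC, kang);
    angle_term(ai(i, 0), ai(i, 1), ai(i, 4), a_ncacb, kang);
    angle_term(ai(i, 2), ai(i, 1), ai(i, 4), a_ccacb, kang);
    improper_term(ai(i, 0), ai(i, 2), ai(i, 1), ai(i, 4), t_cb); // chirality
    if (i + 1 < L) {
      bond_term(ai(i, 2), ai(i + 1, 0), b_CN);
      angle_term(ai(i, 1), ai(i, 2), ai(i + 1, 0), a_CACN, kang);
      angle_term(ai(i, 3), ai(i, 2), ai(i + 1, 0), a_OCN, kang);
      angle_term(ai(i, 2), ai(i + 1, 0), ai(i + 1, 1), a_CNCA, kang);
      // carbonyl O anti to the next amide N about the CA-C axis
      improper_term(ai(i + 1, 0), ai(i, 1), ai(i, 2), ai(i, 3), M_PI);
      // peptide-bond planarity (trans)
      double v = dihedral_val_grad(at(coords, i, 1), at(coords, i, 2),
                                   at(coords, i + 1, 0), at(coords, i + 1, 1),
                                   ga, gb, gc, gd, want_grad);
      if (!ISNAN(v)) {
        double dev = wrap_pi(v - M_PI);
        e_omg += komega * dev * dev;
        double w = w_omg * 2.0 * komega * dev;
        G.add(ai(i, 1), ga, w); G.add(ai(i, 2), gb, w);
        G.add(ai(i + 1, 0), gc, w); G.add(ai(i + 1, 1), gd, w);
      }
    } else {
      angle_term(ai(i, 1), ai(i, 2), ai(i, 3), a_CACO, kang);
    }
  }
  // CA-C-O angle for non-terminal residues too (O geometry)
  for (int i = 0; i + 1 < L; ++i)
    angle_term(ai(i, 1), ai(i, 2), ai(i, 3), a_CACO, kang);

  double total = w_pair * e_dist + w_dih * e_dih + w_ang * e_ang +
                 w_ster * e_ster + w_breg * e_breg + w_omg * e_omg;

  List out = List::create(
      _["energy"] = total,
      _["terms"] = NumericVector::create(
          _["dist"] = e_dist, _["dihedral"] = e_dih, _["angle"] = e_ang,
          _["steric"] = e_ster, _["bonded"] = e_breg, _["omega"] = e_omg));
  if (want_grad) out["grad"] = NumericVector(grad.begin(), grad.end());
  return out;
}
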