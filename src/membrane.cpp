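// Compiled force accumulators for the two membrane constitutive models.
// The mesh topology arrives pre-extracted from R (0-based index vectors);
// geometry is recomputed here each call.  The R-level implementations in
// R/material_new.R and R/material_spectrin.R define the reference
// semantics; these kernels must agree with them to rounding error (a
// cross-check test enforces this).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  V3 operator+(const V3& o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator-(const V3& o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
  V3& operator+=(const V3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  double dot(const V3& o) const { return x * o.x + y * o.y + z * o.z; }
  V3 cross(const V3& o) const {
    return V3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

inline V3 getv(const NumericMatrix& m, int i) {
  return V3(m(i, 0), m(i, 1), m(i, 2));
}
inline void addv(NumericMatrix& m, int i, const V3& v) {
  m(i, 0) += v.x; m(i, 1) += v.y; m(i, 2) += v.z;
}

struct FaceGeom {
  std::vector<V3> nhat, centroid;   // unit normal, centroid
  std::vector<double> area;
};

FaceGeom face_geometry(const NumericMatrix& pos, const IntegerMatrix& faces) {
  int m = faces.nrow();
  FaceGeom g;
  g.nhat.resize(m); g.centroid.resize(m); g.area.resize(m);
  for (int k = 0; k < m; ++k) {
    V3 p0 = getv(pos, faces(k, 0)), p1 = getv(pos, faces(k, 1)),
       p2 = getv(pos, faces(k, 2));
    V3 cr = (p1 - p0).cross(p2 - p0);
    double a2 = cr.norm();
    g.area[k] = 0.5 * a2;
    g.nhat[k] = cr * (1.0 / a2);
    g.centroid[k] = (p0 + p1 + p2) * (1.0 / 3.0);
  }
  return g;
}

double enclosed_volume(const NumericMatrix& pos, const IntegerMatrix& faces) {
  double v = 0;
  for (int k = 0; k < faces.nrow(); ++k) {
    V3 p0 = getv(pos, faces(k, 0)), p1 = getv(pos, faces(k, 1)),
       p2 = getv(pos, faces(k, 2));
    v += p0.dot(p1.cross(p2));
  }
  return v / 6.0;
}

// signed dihedral: edge a->b oriented as traversed by face1, apexes c1, c2
inline double dihedral(const V3& a, const V3& b, const V3& c1, const V3& c2) {
  V3 e = b - a;
  V3 n1 = e.cross(c1 - a);          // face1 = (a, b, c1)
  V3 n2 = (a - b).cross(c2 - b);    // face2 = (b, a, c2)
  double C = n1.dot(n2);
  double S = n1.cross(n2).dot(e) / e.norm();
  return std::atan2(S, C);
}

[[noreturn]] void strain_error(const char* what, int idx, double val,
                               double tau) {
  stop("diverging %s strain at element %d: |strain| = %.6g, limit tau = %g",
       what, idx + 1, std::fabs(val), tau);
}

inline void check_tau(double x, double tau, const char* what, int idx) {
  if (!std::isfinite(x) || std::fabs(x) >= tau - 1e-6)
    strain_error(what, idx, x, tau);
}

}  // namespace

// topology: list with 0-based integer vectors ea, eb (oriented by face 1
// where interior), interior (indices into edges), if1, if2, ap1, ap2
// (per *interior* edge), faces (m x 3), plus logical `closed`.

// [[Rcpp::export(name = ".forces_new_cpp")]]
NumericMatrix forces_new_cpp(const NumericMatrix& pos, const List& topo,
                             const List& ref, const List& par) {
  const IntegerVector ea = topo["ea"], eb = topo["eb"],
                      interior = topo["interior"], if1 = topo["if1"],
                      if2 = topo["if2"], ap1 = topo["ap1"],
                      ap2 = topo["ap2"];
  const IntegerMatrix faces = topo["faces"];
  const bool closed = as<bool>(topo["closed"]);
  const NumericVector L0 = ref["L0"], theta0 = ref["theta0"],
                      A0k = ref["A0_k"];
  const double V0 = as<double>(ref["V0"]);
  const double L0m = as<double>(ref["L0_mean"]);
  const double kBT = as<double>(par["kBT"]);
  const double scale = as<double>(par["stiffness_scale"]);
  const double kl = as<double>(par["kappa_l"]) * scale * kBT;
  const double kb = as<double>(par["kappa_b"]) * scale * kBT;
  const double ka = as<double>(par["kappa_a"]) * scale * kBT;
  const double kv = as<double>(par["kappa_v"]) * kBT;
  const double tl = as<double>(par["tau_l"]), tb = as<double>(par["tau_b"]),
               ta = as<double>(par["tau_a"]), tv = as<double>(par["tau_v"]);
  const double pp = as<double>(par["p"]);
  const bool printed_variant = as<std::string>(par["bending_variant"]) ==
                               "printed";

  const int n = pos.nrow(), ne = ea.size(), nf = faces.nrow();
  NumericMatrix f(n, 3);
  FaceGeom fg = face_geometry(pos, faces);

  // link forces
  for (int i = 0; i < ne; ++i) {
    V3 d = getv(pos, eb[i]) - getv(pos, ea[i]);
    double L = d.norm();
    double dL = (L - L0[i]) / L0[i];
    check_tau(dL, tl, "link", i);
    double Fm = -(kl * dL / pp) * (1.0 + 1.0 / (tl * tl - dL * dL));
    V3 u = d * (1.0 / L);
    addv(f, ea[i], u * (-Fm));
    addv(f, eb[i], u * Fm);
  }

  // bending forces on interior-edge stencils
  for (int j = 0; j < interior.size(); ++j) {
    int i = interior[j];
    int a = ea[i], b = eb[i], c1 = ap1[j], c2 = ap2[j];
    double th = dihedral(getv(pos, a), getv(pos, b), getv(pos, c1),
                         getv(pos, c2));
    double dth = th - theta0[i];
    check_tau(dth, tb, "bending", i);
    double Fm = -(kb * dth / L0m) * (1.0 + 1.0 / (tb * tb - dth * dth));
    const V3& n1 = fg.nhat[if1[j]];
    const V3& n2 = fg.nhat[if2[j]];
    V3 half = (n1 + n2) * (-0.5 * Fm);
    int v1 = a, v2 = printed_variant ? c1 : b;
    int v3 = printed_variant ? b : c1, v4 = c2;
    addv(f, v1, n1 * Fm);
    addv(f, v2, n2 * Fm);
    addv(f, v3, half);
    addv(f, v4, half);
  }

  // local-area forces
  for (int k = 0; k < nf; ++k) {
    double dA = (fg.area[k] - A0k[k]) / A0k[k];
    check_tau(dA, ta, "area", k);
    double Fm = -(ka * dA / L0m) * (1.0 + 1.0 / (ta * ta - dA * dA));
    for (int m = 0; m < 3; ++m) {
      int vm = faces(k, m);
      addv(f, vm, (fg.centroid[k] - getv(pos, vm)) * (-Fm));
    }
  }

  // volume forces
  if (closed) {
    double V = enclosed_volume(pos, faces);
    double dV = (V - V0) / V0;
    check_tau(dV, tv, "volume", 0);
    double Fm = -(kv * dV / L0m) / (tv * tv - dV * dV);
    double Savg = 0;
    for (int k = 0; k < nf; ++k) Savg += fg.area[k];
    Savg /= nf;
    for (int k = 0; k < nf; ++k) {
      V3 w = fg.nhat[k] * (Fm * fg.area[k] / Savg);
      for (int m = 0; m < 3; ++m) addv(f, faces(k, m), w);
    }
  }
  return f;
}

// [[Rcpp::export(name = ".forces_spectrin_cpp")]]
NumericMatrix forces_spectrin_cpp(const NumericMatrix& pos,
                                  const Nullable<NumericMatrix>& vel_,
                                  const List& topo, const List& ref,
                                  const List& par) {
  const IntegerVector ea = topo["ea"], eb = topo["eb"],
                      interior = topo["interior"], if1 = topo["if1"],
                      if2 = topo["if2"], ap1 = topo["ap1"],
                      ap2 = topo["ap2"];
  const IntegerMatrix faces = topo["faces"];
  const bool closed = as<bool>(topo["closed"]);
  const NumericVector L0 = ref["L0"], theta0 = ref["theta0"],
                      A0k = ref["A0_k"];
  const double V0 = as<double>(ref["V0"]), A0 = as<double>(ref["A0"]);
  const double kBT = as<double>(par["kBT"]);
  const double kap_t = as<double>(par["kappa_tilde"]);
  const double kV = as<double>(par["kV"]), kA = as<double>(par["kA"]),
               kAl = as<double>(par["kAl"]);
  const double x0 = as<double>(par["x0"]), pp = as<double>(par["p"]),
               q = as<double>(par["q"]);
  const double eta_m = as<double>(par["eta_m"]);
  const bool face_rep = as<std::string>(par["inplane_repulsion"]) == "face";

  const int n = pos.nrow(), ne = ea.size(), nf = faces.nrow();
  NumericMatrix f(n, 3);
  FaceGeom fg = face_geometry(pos, faces);

  // in-plane: WLC tension plus (for the edge variant) per-edge repulsion
  for (int i = 0; i < ne; ++i) {
    V3 d = getv(pos, eb[i]) - getv(pos, ea[i]);
    double l = d.norm(), lm = x0 * L0[i];
    if (l >= lm)
      stop("WLC extension limit reached at edge %d (l/lm = %.4g)", i + 1,
           l / lm);
    double r = l / lm;
    double tens = (kBT / pp) * (0.25 / ((1 - r) * (1 - r)) - 0.25 + r);
    if (!face_rep) {
      double r0 = 1.0 / x0;
      double t0 = (1.0 / pp) * (0.25 / ((1 - r0) * (1 - r0)) - 0.25 + r0);
      double kp = t0 * L0[i] * L0[i] * L0[i] / 2.0;
      tens -= kBT * 2.0 * kp / (l * l * l);
    }
    V3 u = d * (1.0 / l);
    addv(f, ea[i], u * tens);
    addv(f, eb[i], u * (-tens));
  }

  // area-derived terms (global + local + optional per-face repulsion)
  double A = 0;
  for (int k = 0; k < nf; ++k) A += fg.area[k];
  for (int k = 0; k < nf; ++k) {
    double dUdA = kBT * (kAl * (fg.area[k] - A0k[k]) / A0k[k] +
                         kA * (A - A0) / A0);
    if (face_rep) {
      double l0eq = std::sqrt(A0k[k] * 4.0 / std::sqrt(3.0));
      double r0 = 1.0 / x0, lmq = x0 * l0eq;
      double Al0 = std::sqrt(3.0) * l0eq * l0eq / 4.0;
      double Cq = std::sqrt(3.0) * Al0 * Al0 *
                  (4 * r0 * r0 - 9 * r0 + 6) /
                  (4.0 * pp * lmq * (1 - r0) * (1 - r0));
      dUdA -= kBT * q * Cq / std::pow(fg.area[k], q + 1);
    }
    V3 p0 = getv(pos, faces(k, 0)), p1 = getv(pos, faces(k, 1)),
       p2 = getv(pos, faces(k, 2));
    addv(f, faces(k, 0), fg.nhat[k].cross(p2 - p1) * (-0.5 * dUdA));
    addv(f, faces(k, 1), fg.nhat[k].cross(p0 - p2) * (-0.5 * dUdA));
    addv(f, faces(k, 2), fg.nhat[k].cross(p1 - p0) * (-0.5 * dUdA));
  }

  // volume conservation
  if (closed) {
    double V = enclosed_volume(pos, faces);
    double dUdV = kBT * kV * (V - V0) / V0;
    for (int k = 0; k < nf; ++k) {
      V3 p0 = getv(pos, faces(k, 0)), p1 = getv(pos, faces(k, 1)),
         p2 = getv(pos, faces(k, 2));
      addv(f, faces(k, 0), p1.cross(p2) * (-dUdV / 6.0));
      addv(f, faces(k, 1), p2.cross(p0) * (-dUdV / 6.0));
      addv(f, faces(k, 2), p0.cross(p1) * (-dUdV / 6.0));
    }
  }

  // bending: exact gradient of kappa_tilde (1 - cos(theta - theta0))
  for (int j = 0; j < interior.size(); ++j) {
    int i = interior[j];
    V3 x1 = getv(pos, ea[i]), x2 = getv(pos, eb[i]);
    V3 x3 = getv(pos, ap1[j]), x4 = getv(pos, ap2[j]);
    V3 e = x2 - x1;
    double elen = e.norm();
    V3 n1 = e.cross(x3 - x1);
    V3 n2 = (x1 - x2).cross(x4 - x2);
    double C = n1.dot(n2);
    double S = n1.cross(n2).dot(e);
    double Q = S / elen;
    double th = std::atan2(Q, C);
    double dUdth = kBT * kap_t * std::sin(th - theta0[i]);
    double denom = C * C + Q * Q;
    V3 v1 = x3 - x1, v2 = x4 - x2;
    // gradient building blocks (see R/material_spectrin.R for derivation)
    V3 aC_n1u = v1.cross(n2), aC_n1v = n2.cross(e);
    V3 aC_n2u = v2.cross(n1), aC_n2v = n1.cross(e * (-1.0));
    V3 b1 = n2.cross(e), b2 = e.cross(n1);
    V3 aS_n1u = v1.cross(b1), aS_n1v = b1.cross(e);
    V3 aS_n2u = v2.cross(b2), aS_n2v = b2.cross(e * (-1.0));
    V3 m12 = n1.cross(n2);
    V3 ehat = e * (1.0 / elen);

    V3 gC[4] = {
      aC_n1u * (-1.0) + aC_n1v * (-1.0) + aC_n2u,
      aC_n1u + aC_n2u * (-1.0) + aC_n2v * (-1.0),
      aC_n1v,
      aC_n2v };
    V3 gS[4] = {
      aS_n1u * (-1.0) + aS_n1v * (-1.0) + aS_n2u + m12 * (-1.0),
      aS_n1u + aS_n2u * (-1.0) + aS_n2v * (-1.0) + m12,
      aS_n1v,
      aS_n2v };
    int verts[4] = {ea[i], eb[i], ap1[j], ap2[j]};
    for (int t = 0; t < 4; ++t) {
      V3 gQ = gS[t] * (1.0 / elen);
      if (t == 0) gQ += ehat * (Q / elen);
      if (t == 1) gQ += ehat * (-Q / elen);
      V3 gth = (gQ * C - gC[t] * Q) * (1.0 / denom);
      addv(f, verts[t], gth * (-dUdth));
    }
  }

  // dissipative membrane-viscosity force
  if (vel_.isNotNull() && eta_m > 0) {
    NumericMatrix vel(vel_);
    double gamma_t = std::sqrt(3.0) * eta_m * 1e6;  // Pa s -> pN us/um
    for (int i = 0; i < ne; ++i) {
      V3 dv = getv(vel, ea[i]) - getv(vel, eb[i]);
      addv(f, ea[i], dv * (-gamma_t));
      addv(f, eb[i], dv * gamma_t);
    }
  }
  return f;
}
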