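// Force-bias packing of ellipsoids in a periodic box: Perram-Wertheim
// contact function (exact no-overlap certificate), Monte-Carlo overlap
// volumes (the repulsive potential), and the contraction loop.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct M3 { double m[3][3]; };

// rotation matrix from a unit quaternion (w, x, y, z)
M3 quat_rot(double w, double x, double y, double z) {
  M3 R;
  R.m[0][0] = 1 - 2 * (y * y + z * z);
  R.m[0][1] = 2 * (x * y - w * z);
  R.m[0][2] = 2 * (x * z + w * y);
  R.m[1][0] = 2 * (x * y + w * z);
  R.m[1][1] = 1 - 2 * (x * x + z * z);
  R.m[1][2] = 2 * (y * z - w * x);
  R.m[2][0] = 2 * (x * z - w * y);
  R.m[2][1] = 2 * (y * z + w * x);
  R.m[2][2] = 1 - 2 * (x * x + y * y);
  return R;
}

// Ainv = R diag(a^2, b^2, c^2) R^T  (inverse of the ellipsoid matrix)
M3 ellipsoid_Ainv(const M3& R, double a, double b, double c) {
  double d[3] = {a * a, b * b, c * c};
  M3 out;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += R.m[i][k] * d[k] * R.m[j][k];
      out.m[i][j] = s;
    }
  return out;
}

// q(lambda) = lam (1-lam) r^T [lam B + (1-lam) A]^{-1} r  via 3x3 solve
double pw_eval(double lam, const M3& A, const M3& B, const double r[3]) {
  double C[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[i][j] = lam * B.m[i][j] + (1 - lam) * A.m[i][j];
  // adjugate inverse
  double det = C[0][0] * (C[1][1] * C[2][2] - C[1][2] * C[2][1]) -
               C[0][1] * (C[1][0] * C[2][2] - C[1][2] * C[2][0]) +
               C[0][2] * (C[1][0] * C[2][1] - C[1][1] * C[2][0]);
  double x[3];
  double adj[3][3];
  adj[0][0] =  (C[1][1] * C[2][2] - C[1][2] * C[2][1]);
  adj[0][1] = -(C[0][1] * C[2][2] - C[0][2] * C[2][1]);
  adj[0][2] =  (C[0][1] * C[1][2] - C[0][2] * C[1][1]);
  adj[1][0] = -(C[1][0] * C[2][2] - C[1][2] * C[2][0]);
  adj[1][1] =  (C[0][0] * C[2][2] - C[0][2] * C[2][0]);
  adj[1][2] = -(C[0][0] * C[1][2] - C[0][2] * C[1][0]);
  adj[2][0] =  (C[1][0] * C[2][1] - C[1][1] * C[2][0]);
  adj[2][1] = -(C[0][0] * C[2][1] - C[0][1] * C[2][0]);
  adj[2][2] =  (C[0][0] * C[1][1] - C[0][1] * C[1][0]);
  for (int i = 0; i < 3; ++i)
    x[i] = (adj[i][0] * r[0] + adj[i][1] * r[1] + adj[i][2] * r[2]) / det;
  double q = r[0] * x[0] + r[1] * x[1] + r[2] * x[2];
  return lam * (1 - lam) * q;
}

// Perram-Wertheim contact value F: F > 1 iff the ellipsoids are disjoint;
// both ellipsoids uniformly scaled by s have contact value F / s^2, so the
// touching scale of the pair is sqrt(F).
double pw_contact(const M3& A, const M3& B, const double r[3]) {
  // golden-section maximization of the unimodal pw_eval over lambda
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double lo = 0.0, hi = 1.0;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = pw_eval(x1, A, B, r), f2 = pw_eval(x2, A, B, r);
  for (int it = 0; it < 60; ++it) {
    if (f1 < f2) {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo); f2 = pw_eval(x2, A, B, r);
    } else {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo); f1 = pw_eval(x1, A, B, r);
    }
  }
  return std::max(f1, f2);
}

struct Particle {
  double c[3];        // center
  double ax[3];       // semi-axes
  M3 R;               // rotation
  M3 Ainv;            // at scale 1
  double rad;         // max semi-axis
  double rscale;      // (abc)^(1/3), the scaling radius
  double vol;         // ellipsoid volume
};

inline void min_image(double d[3], const double L[3]) {
  for (int k = 0; k < 3; ++k) d[k] -= L[k] * std::round(d[k] / L[k]);
}

// is point p (absolute) inside particle q scaled by s, under periodicity
inline bool inside(const Particle& P, double s, const double p[3],
                   const double L[3]) {
  double d[3] = {p[0] - P.c[0], p[1] - P.c[1], p[2] - P.c[2]};
  min_image(d, L);
  // u = R^T d, then sum (u_k / (s a_k))^2 <= 1
  double q = 0;
  for (int k = 0; k < 3; ++k) {
    double u = P.R.m[0][k] * d[0] + P.R.m[1][k] * d[1] + P.R.m[2][k] * d[2];
    q += (u / (s * P.ax[k])) * (u / (s * P.ax[k]));
  }
  return q <= 1.0;
}

std::vector<Particle> build_particles(const NumericMatrix& centers,
                                      const NumericMatrix& axes,
                                      const NumericMatrix& quats) {
  int n = centers.nrow();
  std::vector<Particle> P(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      P[i].c[k] = centers(i, k);
      P[i].ax[k] = axes(i, k);
    }
    P[i].R = quat_rot(quats(i, 0), quats(i, 1), quats(i, 2), quats(i, 3));
    P[i].Ainv = ellipsoid_Ainv(P[i].R, P[i].ax[0], P[i].ax[1], P[i].ax[2]);
    P[i].rad = std::max(P[i].ax[0], std::max(P[i].ax[1], P[i].ax[2]));
    P[i].rscale = std::cbrt(P[i].ax[0] * P[i].ax[1] * P[i].ax[2]);
    P[i].vol = 4.0 / 3.0 * M_PI * P[i].ax[0] * P[i].ax[1] * P[i].ax[2];
  }
  return P;
}

// largest uniform scaling with zero overlaps (min over pairs of sqrt(F)),
// with a cheap center-distance lower bound to skip far pairs
double compute_din(const std::vector<Particle>& P, const double L[3]) {
  int n = P.size();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d[3] = {P[j].c[0] - P[i].c[0], P[j].c[1] - P[i].c[1],
                     P[j].c[2] - P[i].c[2]};
      min_image(d, L);
      double dist = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (dist / (P[i].rad + P[j].rad) >= best) continue;
      double F = pw_contact(P[i].Ainv, P[j].Ainv, d);
      double s = std::sqrt(F);
      if (s < best) best = s;
    }
  return best;
}

// MC overlap volume of particles i, j scaled by s (sampling the smaller)
double mc_overlap(const Particle& Pi, const Particle& Pj, double si,
                  double sj, const double L[3], int nsamp,
                  std::mt19937_64& rng) {
  const Particle& S = (Pi.vol * si * si * si <= Pj.vol * sj * sj * sj) ? Pi : Pj;
  const Particle& O = (&S == &Pi) ? Pj : Pi;
  double ss = (&S == &Pi) ? si : sj, so = (&S == &Pi) ? sj : si;
  std::uniform_real_distribution<double> U(-1.0, 1.0);
  int hit = 0;
  for (int t = 0; t < nsamp; ++t) {
    // rejection-sample the unit ball, map into the scaled ellipsoid frame
    double u[3];
    do {
      u[0] = U(rng); u[1] = U(rng); u[2] = U(rng);
    } while (u[0] * u[0] + u[1] * u[1] + u[2] * u[2] > 1.0);
    double p[3];
    for (int k = 0; k < 3; ++k)
      p[k] = S.c[k] + S.R.m[k][0] * (ss * S.ax[0] * u[0]) +
             S.R.m[k][1] * (ss * S.ax[1] * u[1]) +
             S.R.m[k][2] * (ss * S.ax[2] * u[2]);
    if (inside(O, so, p, L)) ++hit;
  }
  return S.vol * ss * ss * ss * (double)hit / nsamp;
}

// quaternion product: out = a * b  (w, x, y, z)
inline void quat_mul(const double a[4], const double b[4], double out[4]) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

// apply the axis-angle rotation w (length = angle) to particle P
void rotate_particle(Particle& P, double q[4], const double w[3]) {
  double ang = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (ang < 1e-14) return;
  double h = 0.5 * ang, s = std::sin(h) / ang;
  double dq[4] = {std::cos(h), s * w[0], s * w[1], s * w[2]};
  double qn[4];
  quat_mul(dq, q, qn);
  double nn = std::sqrt(qn[0] * qn[0] + qn[1] * qn[1] + qn[2] * qn[2] +
                        qn[3] * qn[3]);
  for (int k = 0; k < 4; ++k) q[k] = qn[k] / nn;
  P.R = quat_rot(q[0], q[1], q[2], q[3]);
  P.Ainv = ellipsoid_Ainv(P.R, P.ax[0], P.ax[1], P.ax[2]);
}

// numeric gradient of sqrt(F_PW) w.r.t. a small rotation of particle i
// about each coordinate axis (r is the minimum-image c_j - c_i)
void pw_rot_gradient(const Particle& Pi, const Particle& Pj,
                     const double r[3], const double qi[4], double grad[3]) {
  const double h = 1e-4;
  double base = std::sqrt(pw_contact(Pi.Ainv, Pj.Ainv, r));
  for (int ax = 0; ax < 3; ++ax) {
    double w[3] = {0, 0, 0};
    w[ax] = h;
    Particle tmp = Pi;
    double q[4] = {qi[0], qi[1], qi[2], qi[3]};
    rotate_particle(tmp, q, w);
    grad[ax] = (std::sqrt(pw_contact(tmp.Ainv, Pj.Ainv, r)) - base) / h;
  }
}

}  // namespace

// [[Rcpp::export(name = ".pw_contact_cpp")]]
double pw_contact_cpp(const NumericMatrix& centers, const NumericMatrix& axes,
                      const NumericMatrix& quats, const NumericVector& domain) {
  std::vector<Particle> P = build_particles(centers, axes, quats);
  double L[3] = {domain[0], domain[1], domain[2]};
  double d[3] = {P[1].c[0] - P[0].c[0], P[1].c[1] - P[0].c[1],
                 P[1].c[2] - P[0].c[2]};
  min_image(d, L);
  return pw_contact(P[0].Ainv, P[1].Ainv, d);
}

// [[Rcpp::export(name = ".din_cpp")]]
double din_cpp(const NumericMatrix& centers, const NumericMatrix& axes,
               const NumericMatrix& quats, const NumericVector& domain) {
  std::vector<Particle> P = build_particles(centers, axes, quats);
  double L[3] = {domain[0], domain[1], domain[2]};
  return compute_din(P, L);
}

// [[Rcpp::export(name = ".mc_overlap_cpp")]]
double mc_overlap_cpp(const NumericMatrix& centers, const NumericMatrix& axes,
                      const NumericMatrix& quats, double scale,
                      const NumericVector& domain, int mc_samples, int seed) {
  std::vector<Particle> P = build_particles(centers, axes, quats);
  double L[3] = {domain[0], domain[1], domain[2]};
  double d[3] = {P[1].c[0] - P[0].c[0], P[1].c[1] - P[0].c[1],
                 P[1].c[2] - P[0].c[2]};
  min_image(d, L);
  if (pw_contact(P[0].Ainv, P[1].Ainv, d) >= scale * scale)
    return 0.0;   // disjoint at this scale: exact zero
  std::mt19937_64 rng(seed);
  return mc_overlap(P[0], P[1], scale, scale, L, mc_samples, rng);
}

// fraction of the box covered by the union of the ellipsoids scaled by s
// [[Rcpp::export(name = ".union_fraction_cpp")]]
double union_fraction_cpp(const NumericMatrix& centers,
                          const NumericMatrix& axes,
                          const NumericMatrix& quats, double scale,
                          const NumericVector& domain, int nsamp, int seed) {
  std::vector<Particle> P = build_particles(centers, axes, quats);
  double L[3] = {domain[0], domain[1], domain[2]};
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  int hit = 0;
  for (int t = 0; t < nsamp; ++t) {
    double p[3] = {U(rng) * L[0], U(rng) * L[1], U(rng) * L[2]};
    for (size_t i = 0; i < P.size(); ++i)
      if (inside(P[i], scale, p, L)) { ++hit; break; }
  }
  return (double)hit / nsamp;
}

// The force-bias contraction loop.  All particles share the scalar pair
// (d_in, d_out); d_out never contracts below 1 so that termination
// (d_out <= d_in) certifies an overlap-free configuration at scale 1.
// [[Rcpp::export(name = ".pack_cpp")]]
List pack_cpp(const NumericMatrix& centers, const NumericMatrix& axes,
              const NumericMatrix& quats, const NumericVector& domain,
              double d_out0, double contraction_rate, int max_iterations,
              int mc_samples, double step_length, double jitter,
              bool rotate, double rot_step, int seed) {
  std::vector<Particle> P = build_particles(centers, axes, quats);
  int n = P.size();
  double L[3] = {domain[0], domain[1], domain[2]};
  std::mt19937_64 rng(seed);
  std::vector<double> Q(4 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 4; ++k) Q[4 * i + k] = quats(i, k);
  std::vector<double> rot;
  if (rotate) rot.resize(3 * n);

  double mean_vol = 0, mean_rscale = 0;
  for (int i = 0; i < n; ++i) {
    mean_vol += P[i].vol;
    mean_rscale += P[i].rscale;
  }
  mean_vol /= n; mean_rscale /= n;

  double d_out = d_out0;
  double d_in = compute_din(P, L);
  std::vector<double> din_log, dout_log;
  int iter = 0;
  bool converged = d_out <= d_in;
  std::vector<double> disp(3 * n);

  while (!converged && iter < max_iterations) {
    ++iter;
    std::fill(disp.begin(), disp.end(), 0.0);
    if (rotate) std::fill(rot.begin(), rot.end(), 0.0);
    // repulsive displacements from overlaps at the d_out scale
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d[3] = {P[j].c[0] - P[i].c[0], P[j].c[1] - P[i].c[1],
                       P[j].c[2] - P[i].c[2]};
        min_image(d, L);
        double dist = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        if (dist >= d_out * (P[i].rad + P[j].rad)) continue;
        double F = pw_contact(P[i].Ainv, P[j].Ainv, d);
        if (F >= d_out * d_out) continue;      // disjoint at d_out
        double p_ij = mc_overlap(P[i], P[j], d_out, d_out, L, mc_samples,
                                 rng) / mean_vol;
        // pair displacement magnitude: the overlap-volume potential plus a
        // geometric de-overlap term (a fraction of the center-line
        // separation still needed at the d_out scale), which keeps shallow
        // overlaps below the MC resolution active and is self-limiting
        double need = dist * (d_out / std::sqrt(F) - 1.0);
        double mag = step_length * p_ij + 0.5 * need;
        if (mag <= 0) continue;
        double u[3];
        if (dist > 1e-12) {
          for (int k = 0; k < 3; ++k) u[k] = d[k] / dist;
        } else {                                // coincident centers
          u[0] = 1; u[1] = 0; u[2] = 0;
        }
        // heavier (larger) particles move less: mass ~ scaling radius;
        // the weights of a pair sum to 1 so the pair opens by `mag`
        double wi = (1.0 / P[i].rscale) / (1.0 / P[i].rscale + 1.0 / P[j].rscale);
        double wj = 1.0 - wi;
        for (int k = 0; k < 3; ++k) {
          disp[3 * i + k] -= mag * u[k] * wi;
          disp[3 * j + k] += mag * u[k] * wj;
        }
        if (rotate) {
          // rotate both particles toward larger clearance (gradient ascent
          // on the pair contact scale)
          double gi[3], gj[3];
          double rij[3] = {d[0], d[1], d[2]};
          double rji[3] = {-d[0], -d[1], -d[2]};
          pw_rot_gradient(P[i], P[j], rij, &Q[4 * i], gi);
          pw_rot_gradient(P[j], P[i], rji, &Q[4 * j], gj);
          for (int k = 0; k < 3; ++k) {
            rot[3 * i + k] += rot_step * gi[k] * wi;
            rot[3 * j + k] += rot_step * gj[k] * wj;
          }
        }
      }
    // apply with a per-particle displacement cap, wrap periodically;
    // particles under contact force receive a small random annealing kick
    // that breaks force-balanced (jammed) local arrangements
    std::normal_distribution<double> N(0.0, 1.0);
    for (int i = 0; i < n; ++i) {
      double dn = std::sqrt(disp[3 * i] * disp[3 * i] +
                            disp[3 * i + 1] * disp[3 * i + 1] +
                            disp[3 * i + 2] * disp[3 * i + 2]);
      double cap = 0.25 * P[i].rscale;
      double f = (dn > cap) ? cap / dn : 1.0;
      double kick[3] = {0, 0, 0};
      if (jitter > 0 && dn > 0) {
        for (int k = 0; k < 3; ++k) kick[k] = N(rng);
        double kn = std::sqrt(kick[0] * kick[0] + kick[1] * kick[1] +
                              kick[2] * kick[2]);
        for (int k = 0; k < 3; ++k)
          kick[k] *= jitter * P[i].rscale / kn;
      }
      for (int k = 0; k < 3; ++k) {
        P[i].c[k] += f * disp[3 * i + k] + kick[k];
        P[i].c[k] -= L[k] * std::floor(P[i].c[k] / L[k]);
      }
      if (rotate) {
        double w[3] = {rot[3 * i], rot[3 * i + 1], rot[3 * i + 2]};
        double wn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
        if (wn > 0.2)                       // rotation cap, rad
          for (int k = 0; k < 3; ++k) w[k] *= 0.2 / wn;
        rotate_particle(P[i], &Q[4 * i], w);
      }
    }
    d_out = std::max(d_out * contraction_rate, 1.0);
    d_in = compute_din(P, L);
    din_log.push_back(d_in);
    dout_log.push_back(d_out);
    converged = d_out <= d_in;
    if (iter % 64 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out_centers(n, 3), out_quats(n, 4);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) out_centers(i, k) = P[i].c[k];
    for (int k = 0; k < 4; ++k) out_quats(i, k) = Q[4 * i + k];
  }
  return List::create(_["centers"] = out_centers,
                      _["orientations"] = out_quats, _["d_in"] = d_in,
                      _["d_out"] = d_out, _["iterations"] = iter,
                      _["converged"] = converged,
                      _["din_log"] = wrap(din_log),
                      _["dout_log"] = wrap(dout_log));
}
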