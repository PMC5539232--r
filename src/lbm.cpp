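// Minimal D3Q19 BGK lattice-Boltzmann solver with Guo forcing, link-wise
// (halfway) bounce-back against an optional solid mask with prescribed
// wall velocities, periodic boundaries elsewhere, and Peskin 4-point
// immersed-boundary coupling.  Sufficient for one suspended cell in
// wall-driven shear or a narrow channel.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// membrane force kernels (membrane.cpp)
NumericMatrix forces_new_cpp(const NumericMatrix& pos, const List& topo,
                             const List& ref, const List& par);
NumericMatrix forces_spectrin_cpp(const NumericMatrix& pos,
                                  const Nullable<NumericMatrix>& vel_,
                                  const List& topo, const List& ref,
                                  const List& par);

namespace {

const int Q = 19;
const int cx[Q] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
const int cy[Q] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
const int cz[Q] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
const double w0 = 1.0 / 3.0, w1 = 1.0 / 18.0, w2 = 1.0 / 36.0;
const double W[Q] = {w0, w1, w1, w1, w1, w1, w1, w2, w2, w2, w2, w2, w2,
                     w2, w2, w2, w2, w2, w2};
int OPP[Q];

struct Grid {
  int nx, ny, nz, N;
  inline int idx(int x, int y, int z) const { return x + nx * (y + ny * z); }
};

void init_opp() {
  for (int i = 0; i < Q; ++i)
    for (int j = 0; j < Q; ++j)
      if (cx[j] == -cx[i] && cy[j] == -cy[i] && cz[j] == -cz[i]) OPP[i] = j;
}

inline int wrap(int a, int n) { return (a % n + n) % n; }

// equilibrium distribution
inline double feq(int i, double rho, double ux, double uy, double uz) {
  double cu = cx[i] * ux + cy[i] * uy + cz[i] * uz;
  double u2 = ux * ux + uy * uy + uz * uz;
  return W[i] * rho * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * u2);
}

// one BGK collision + streaming pass.  fin/fout are Q x N (component-major
// blocks).  solid: 0 fluid, 1 solid; uw: 3 x N wall velocities (lattice).
// force: 3 x N lattice force field (Guo).
void step_core(const double* fin, double* fout, const Grid& g, double tau,
               const int* solid, const double* uw, const double* force,
               double* rho_out, double* u_out) {
  const double omega = 1.0 / tau;
  const double fpref = 1.0 - 0.5 / tau;
  std::vector<double> fpost((size_t)Q * g.N);
  // collision (fluid nodes only)
  for (int n = 0; n < g.N; ++n) {
    if (solid[n]) {
      for (int i = 0; i < Q; ++i) fpost[(size_t)i * g.N + n] = fin[(size_t)i * g.N + n];
      continue;
    }
    double rho = 0, mx = 0, my = 0, mz = 0;
    for (int i = 0; i < Q; ++i) {
      double fi = fin[(size_t)i * g.N + n];
      rho += fi;
      mx += fi * cx[i]; my += fi * cy[i]; mz += fi * cz[i];
    }
    double Fx = force ? force[n] : 0.0;
    double Fy = force ? force[g.N + n] : 0.0;
    double Fz = force ? force[2 * g.N + n] : 0.0;
    double ux = (mx + 0.5 * Fx) / rho;
    double uy = (my + 0.5 * Fy) / rho;
    double uz = (mz + 0.5 * Fz) / rho;
    if (rho_out) rho_out[n] = rho;
    if (u_out) {
      u_out[n] = ux; u_out[g.N + n] = uy; u_out[2 * g.N + n] = uz;
    }
    for (int i = 0; i < Q; ++i) {
      double cu = cx[i] * ux + cy[i] * uy + cz[i] * uz;
      double cF = cx[i] * Fx + cy[i] * Fy + cz[i] * Fz;
      double uF = ux * Fx + uy * Fy + uz * Fz;
      double Si = fpref * W[i] * (3.0 * (cF - uF) + 9.0 * cu * cF);
      size_t k = (size_t)i * g.N + n;
      fpost[k] = fin[k] - omega * (fin[k] - feq(i, rho, ux, uy, uz)) + Si;
    }
  }
  // streaming with link-wise bounce-back at solid neighbors
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        int n = g.idx(x, y, z);
        if (solid[n]) {
          for (int i = 0; i < Q; ++i)
            fout[(size_t)i * g.N + n] = fpost[(size_t)i * g.N + n];
          continue;
        }
        for (int i = 0; i < Q; ++i) {
          int xs = wrap(x - cx[i], g.nx);
          int ys = wrap(y - cy[i], g.ny);
          int zs = wrap(z - cz[i], g.nz);
          int ns = g.idx(xs, ys, zs);
          if (!solid[ns]) {
            fout[(size_t)i * g.N + n] = fpost[(size_t)i * g.N + ns];
          } else {
            // halfway bounce-back from the (possibly moving) wall
            int io = OPP[i];
            double cuw = cx[i] * uw[ns] + cy[i] * uw[g.N + ns] +
                         cz[i] * uw[2 * g.N + ns];
            fout[(size_t)i * g.N + n] =
                fpost[(size_t)io * g.N + n] + 6.0 * W[i] * cuw;
          }
        }
      }
}

// Peskin 4-point kernel
inline double peskin4(double r) {
  double a = std::fabs(r);
  if (a >= 2.0) return 0.0;
  if (a <= 1.0) return 0.125 * (3.0 - 2.0 * a + std::sqrt(1.0 + 4.0 * a - 4.0 * a * a));
  return 0.125 * (5.0 - 2.0 * a - std::sqrt(-7.0 + 12.0 * a - 4.0 * a * a));
}

struct KernelSupport {
  int ix[4], iy[4], iz[4];
  double wx[4], wy[4], wz[4];
};

// lattice coordinates of vertex: node n sits at physical (n + 0.5) dx in
// each direction is a convention choice; here node n sits at n * dx.
bool kernel_at(double gx, double gy, double gz, const Grid& g,
               const int* solid, KernelSupport& K, bool* touches_solid) {
  int bx = (int)std::floor(gx) - 1, by = (int)std::floor(gy) - 1,
      bz = (int)std::floor(gz) - 1;
  *touches_solid = false;
  for (int a = 0; a < 4; ++a) {
    int xx = bx + a, yy = by + a, zz = bz + a;
    K.wx[a] = peskin4(gx - xx);
    K.wy[a] = peskin4(gy - yy);
    K.wz[a] = peskin4(gz - zz);
    K.ix[a] = wrap(xx, g.nx);
    K.iy[a] = wrap(yy, g.ny);
    K.iz[a] = wrap(zz, g.nz);
  }
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      for (int c = 0; c < 4; ++c)
        if (K.wx[a] * K.wy[b] * K.wz[c] > 0 &&
            solid[g.idx(K.ix[a], K.iy[b], K.iz[c])])
          *touches_solid = true;
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".lbm_init_cpp")]]
NumericVector lbm_init_cpp(int nx, int ny, int nz) {
  init_opp();
  Grid g{nx, ny, nz, nx * ny * nz};
  NumericVector f((size_t)Q * g.N);
  for (int i = 0; i < Q; ++i)
    for (int n = 0; n < g.N; ++n) f[(size_t)i * g.N + n] = W[i];
  return f;
}

// [[Rcpp::export(name = ".lbm_step_cpp")]]
List lbm_step_cpp(NumericVector f, IntegerVector dims, double tau,
                  IntegerVector solid, NumericVector uw,
                  Nullable<NumericVector> force_, int nsteps,
                  bool return_macros) {
  init_opp();
  Grid g{dims[0], dims[1], dims[2], dims[0] * dims[1] * dims[2]};
  NumericVector fb((size_t)Q * g.N);
  const double* forcep = nullptr;
  NumericVector force;
  if (force_.isNotNull()) {
    force = NumericVector(force_);
    forcep = REAL(force);
  }
  std::vector<double> rho(g.N), u(3 * g.N);
  double* fa = REAL(f);
  double* fbp = REAL(fb);
  for (int s = 0; s < nsteps; ++s) {
    step_core(fa, fbp, g, tau, INTEGER(solid), REAL(uw), forcep,
              rho.data(), u.data());
    std::swap(fa, fbp);
  }
  NumericVector fout((size_t)Q * g.N);
  std::copy(fa, fa + (size_t)Q * g.N, REAL(fout));
  List out = List::create(_["f"] = fout);
  if (return_macros) {
    // recompute macros from the final state (without forcing correction)
    NumericVector rho_o(g.N), u_o(3 * g.N);
    for (int n = 0; n < g.N; ++n) {
      double r = 0, mx = 0, my = 0, mz = 0;
      for (int i = 0; i < Q; ++i) {
        double fi = fa[(size_t)i * g.N + n];
        r += fi; mx += fi * cx[i]; my += fi * cy[i]; mz += fi * cz[i];
      }
      double Fx = forcep ? forcep[n] : 0, Fy = forcep ? forcep[g.N + n] : 0,
             Fz = forcep ? forcep[2 * g.N + n] : 0;
      rho_o[n] = r;
      u_o[n] = (mx + 0.5 * Fx) / r;
      u_o[g.N + n] = (my + 0.5 * Fy) / r;
      u_o[2 * g.N + n] = (mz + 0.5 * Fz) / r;
    }
    out["rho"] = rho_o;
    out["u"] = u_o;
  }
  return out;
}

// [[Rcpp::export(name = ".ibm_interpolate_cpp")]]
NumericMatrix ibm_interpolate_cpp(NumericVector u, IntegerVector dims,
                                  IntegerVector solid,
                                  const NumericMatrix& verts, double dx) {
  init_opp();
  Grid g{dims[0], dims[1], dims[2], dims[0] * dims[1] * dims[2]};
  int nv = verts.nrow();
  NumericMatrix out(nv, 3);
  KernelSupport K;
  for (int v = 0; v < nv; ++v) {
    bool ts;
    kernel_at(verts(v, 0) / dx, verts(v, 1) / dx, verts(v, 2) / dx, g,
              INTEGER(solid), K, &ts);
    if (ts)
      stop("vertex %d lies within kernel support of a boundary", v + 1);
    double ux = 0, uy = 0, uz = 0;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        for (int c = 0; c < 4; ++c) {
          double wgt = K.wx[a] * K.wy[b] * K.wz[c];
          if (wgt == 0) continue;
          int n = g.idx(K.ix[a], K.iy[b], K.iz[c]);
          ux += wgt * u[n];
          uy += wgt * u[g.N + n];
          uz += wgt * u[2 * g.N + n];
        }
    out(v, 0) = ux; out(v, 1) = uy; out(v, 2) = uz;
  }
  return out;
}

// [[Rcpp::export(name = ".ibm_spread_cpp")]]
NumericVector ibm_spread_cpp(const NumericMatrix& verts,
                             const NumericMatrix& forces,
                             IntegerVector dims, IntegerVector solid,
                             double dx) {
  init_opp();
  Grid g{dims[0], dims[1], dims[2], dims[0] * dims[1] * dims[2]};
  NumericVector out(3 * (size_t)g.N);
  KernelSupport K;
  for (int v = 0; v < verts.nrow(); ++v) {
    bool ts;
    kernel_at(verts(v, 0) / dx, verts(v, 1) / dx, verts(v, 2) / dx, g,
              INTEGER(solid), K, &ts);
    if (ts)
      stop("vertex %d lies within kernel support of a boundary", v + 1);
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        for (int c = 0; c < 4; ++c) {
          double wgt = K.wx[a] * K.wy[b] * K.wz[c];
          if (wgt == 0) continue;
          int n = g.idx(K.ix[a], K.iy[b], K.iz[c]);
          out[n] += wgt * forces(v, 0);
          out[g.N + n] += wgt * forces(v, 1);
          out[2 * g.N + n] += wgt * forces(v, 2);
        }
  }
  return out;
}

// Coupled LBM-IBM run with one membrane.  Physical units: dx um, dt us,
// rho0 pg/um^3; membrane positions um, forces pN.
// [[Rcpp::export(name = ".coupled_run_cpp")]]
List coupled_run_cpp(NumericVector f, IntegerVector dims,
                     IntegerVector solid, NumericVector uw, double tau,
                     double dx, double dt, double rho0,
                     NumericVector body_force_lat, NumericMatrix positions,
                     const List& topo, const List& ref, const List& par,
                     std::string model_kind, int nsteps, int sample_every) {
  init_opp();
  Grid g{dims[0], dims[1], dims[2], dims[0] * dims[1] * dims[2]};
  const IntegerMatrix faces = topo["faces"];
  NumericVector fb((size_t)Q * g.N);
  double* fa = REAL(f);
  double* fbp = REAL(fb);
  std::vector<double> rho(g.N), u(3 * g.N, 0.0), forceLat(3 * g.N);
  double f2l = dt * dt / (rho0 * dx * dx * dx * dx);  // pN -> lattice force
  NumericMatrix pos = clone(positions);
  int nv = pos.nrow();
  KernelSupport K;

  std::vector<double> t_out, dmax_out, vol_out;
  // initial macros
  for (int n = 0; n < g.N; ++n) {
    double r = 0, mx = 0, my = 0, mz = 0;
    for (int i = 0; i < Q; ++i) {
      double fi = fa[(size_t)i * g.N + n];
      r += fi; mx += fi * cx[i]; my += fi * cy[i]; mz += fi * cz[i];
    }
    rho[n] = r; u[n] = mx / r; u[g.N + n] = my / r; u[2 * g.N + n] = mz / r;
  }

  std::vector<double> uv(3 * nv), vnormal(3 * nv);
  for (int s = 0; s < nsteps; ++s) {
    // 1. interpolate the fluid velocity at the membrane vertices
    for (int v = 0; v < nv; ++v) {
      bool ts;
      kernel_at(pos(v, 0) / dx, pos(v, 1) / dx, pos(v, 2) / dx, g,
                INTEGER(solid), K, &ts);
      if (ts)
        stop("membrane vertex %d entered the wall kernel support at step %d",
             v + 1, s);
      double ux = 0, uy = 0, uz = 0;
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
          for (int c = 0; c < 4; ++c) {
            double wgt = K.wx[a] * K.wy[b] * K.wz[c];
            if (wgt == 0) continue;
            int n = g.idx(K.ix[a], K.iy[b], K.iz[c]);
            ux += wgt * u[n]; uy += wgt * u[g.N + n]; uz += wgt * u[2 * g.N + n];
          }
      uv[3 * v] = ux; uv[3 * v + 1] = uy; uv[3 * v + 2] = uz;
    }
    // 2. project out the net transmembrane volumetric flux.  The kernel-
    // smeared membrane is weakly permeable; a pressurized interior (from
    // the quasi-incompressibility force) would otherwise seep fluid
    // through the surface and inflate or deflate the cell without bound.
    // Subtracting the uniform normal velocity that carries the net flux
    // leaves all tangential and deformation components untouched.
    {
      std::fill(vnormal.begin(), vnormal.end(), 0.0);
      for (int k = 0; k < faces.nrow(); ++k) {
        int i0 = faces(k, 0), i1 = faces(k, 1), i2 = faces(k, 2);
        double e1[3], e2[3];
        for (int m = 0; m < 3; ++m) {
          e1[m] = pos(i1, m) - pos(i0, m);
          e2[m] = pos(i2, m) - pos(i0, m);
        }
        double nx = 0.5 * (e1[1] * e2[2] - e1[2] * e2[1]);
        double ny = 0.5 * (e1[2] * e2[0] - e1[0] * e2[2]);
        double nz = 0.5 * (e1[0] * e2[1] - e1[1] * e2[0]);
        for (int m0 = 0; m0 < 3; ++m0) {
          int vv = faces(k, m0);
          vnormal[3 * vv] += nx / 3.0;
          vnormal[3 * vv + 1] += ny / 3.0;
          vnormal[3 * vv + 2] += nz / 3.0;
        }
      }
      double Qflux = 0, Asum = 0;
      for (int v = 0; v < nv; ++v) {
        Qflux += uv[3 * v] * vnormal[3 * v] +
                 uv[3 * v + 1] * vnormal[3 * v + 1] +
                 uv[3 * v + 2] * vnormal[3 * v + 2];
        Asum += std::sqrt(vnormal[3 * v] * vnormal[3 * v] +
                          vnormal[3 * v + 1] * vnormal[3 * v + 1] +
                          vnormal[3 * v + 2] * vnormal[3 * v + 2]);
      }
      if (Asum > 0) {
        double corr = Qflux / Asum;
        for (int v = 0; v < nv; ++v) {
          double nn = std::sqrt(vnormal[3 * v] * vnormal[3 * v] +
                                vnormal[3 * v + 1] * vnormal[3 * v + 1] +
                                vnormal[3 * v + 2] * vnormal[3 * v + 2]);
          if (nn > 0)
            for (int m = 0; m < 3; ++m)
              uv[3 * v + m] -= corr * vnormal[3 * v + m] / nn;
        }
      }
    }
    // 3. advect; positions stay unwrapped (the kernel wraps node indices)
    for (int v = 0; v < nv; ++v) {
      pos(v, 0) += uv[3 * v] * dx;       // lattice u * dt = u * dx
      pos(v, 1) += uv[3 * v + 1] * dx;
      pos(v, 2) += uv[3 * v + 2] * dx;
    }
    // 2. membrane forces at the new configuration
    NumericMatrix fm = (model_kind == "new")
        ? forces_new_cpp(pos, topo, ref, par)
        : forces_spectrin_cpp(pos, R_NilValue, topo, ref, par);
    // 3. spread to the lattice force field
    std::fill(forceLat.begin(), forceLat.end(), 0.0);
    for (int v = 0; v < nv; ++v) {
      bool ts;
      kernel_at(pos(v, 0) / dx, pos(v, 1) / dx, pos(v, 2) / dx, g,
                INTEGER(solid), K, &ts);
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
          for (int c = 0; c < 4; ++c) {
            double wgt = K.wx[a] * K.wy[b] * K.wz[c];
            if (wgt == 0) continue;
            int n = g.idx(K.ix[a], K.iy[b], K.iz[c]);
            forceLat[n] += wgt * fm(v, 0) * f2l;
            forceLat[g.N + n] += wgt * fm(v, 1) * f2l;
            forceLat[2 * g.N + n] += wgt * fm(v, 2) * f2l;
          }
    }
    if (body_force_lat.size() == 3)
      for (int n = 0; n < g.N; ++n)
        if (!INTEGER(solid)[n]) {
          forceLat[n] += body_force_lat[0];
          forceLat[g.N + n] += body_force_lat[1];
          forceLat[2 * g.N + n] += body_force_lat[2];
        }
    // 4. collide + stream
    step_core(fa, fbp, g, tau, INTEGER(solid), REAL(uw), forceLat.data(),
              rho.data(), u.data());
    std::swap(fa, fbp);
    // density (compressibility) guard
    if (s % 50 == 0) {
      for (int n = 0; n < g.N; ++n)
        if (!INTEGER(solid)[n] && std::fabs(rho[n] - 1.0) > 0.05)
          stop("density deviation beyond 5%% at step %d: flow unstable", s);
      Rcpp::checkUserInterrupt();
    }
    if ((s + 1) % sample_every == 0 || s + 1 == nsteps) {
      // max caliper diameter (pairwise) and enclosed volume
      double dmax = 0;
      for (int a = 0; a < nv; ++a)
        for (int b = a + 1; b < nv; ++b) {
          double ddx = pos(a, 0) - pos(b, 0), ddy = pos(a, 1) - pos(b, 1),
                 ddz = pos(a, 2) - pos(b, 2);
          double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (d2 > dmax) dmax = d2;
        }
      double vol = 0;
      for (int k = 0; k < faces.nrow(); ++k) {
        double p0[3], p1[3], p2[3];
        for (int m = 0; m < 3; ++m) {
          p0[m] = pos(faces(k, 0), m);
          p1[m] = pos(faces(k, 1), m);
          p2[m] = pos(faces(k, 2), m);
        }
        vol += p0[0] * (p1[1] * p2[2] - p1[2] * p2[1]) -
               p0[1] * (p1[0] * p2[2] - p1[2] * p2[0]) +
               p0[2] * (p1[0] * p2[1] - p1[1] * p2[0]);
      }
      t_out.push_back((s + 1) * dt);
      dmax_out.push_back(std::sqrt(dmax));
      vol_out.push_back(vol / 6.0);
    }
  }
  NumericVector fout((size_t)Q * g.N);
  std::copy(fa, fa + (size_t)Q * g.N, REAL(fout));
  return List::create(_["f"] = fout, _["positions"] = pos,
                      _["t"] = wrap(t_out), _["d_max"] = wrap(dmax_out),
                      _["volume"] = wrap(vol_out));
}
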