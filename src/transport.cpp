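#include <Rcpp.h>
#include <cmath>
#include <cfloat>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Klein-Nishina differential cross-section, r_e = 1
static inline double kn_dcs(double th, double alpha) {
  double c = std::cos(th);
  double k = 1.0 + alpha * (1.0 - c);
  return 0.5 * (1.0 + c * c + alpha * alpha * (1.0 - c) * (1.0 - c) / k) / (k * k);
}

// Rayleigh differential cross-section with analytic form factor
// F = theta^l * exp(-c2*theta), c1 = 1 (cancels under normalization)
static inline double ray_dcs(double th, double l, double c2) {
  double c = std::cos(th);
  double F = std::pow(th, l) * std::exp(-c2 * th);
  return 0.5 * (1.0 + c * c) * F * F;
}

static inline double u01(void) { return unif_rand(); }

// xi on (0,1]: the free-path equation uses -log(xi)
static inline double xi01(void) {
  double x = 1.0 - unif_rand();
  return (x > 0.0) ? x : DBL_MIN;
}

static const double PI_ = 3.14159265358979323846;

// rejection sampler against a constant envelope; sin_weight multiplies the
// target by sin(theta) (solid-angle convention), off by default upstream
static double sample_theta(bool rayleigh, double alpha, double l, double c2,
                           double env, bool sin_weight) {
  for (int it = 0; it < 100000000; ++it) {
    double th = PI_ * u01();
    double g = rayleigh ? ray_dcs(th, l, c2) : kn_dcs(th, alpha);
    if (sin_weight) g *= std::sin(th);
    if (g > env)
      stop("rejection envelope violated (envelope %g < density %g at theta=%g)",
           env, g, th);
    if (env * u01() <= g) return th;
  }
  stop("rejection sampler failed to accept after 1e8 tries");
  return NA_REAL; // unreachable
}

// [[Rcpp::export]]
NumericVector cpp_sample_compton(int n, double alpha, double env, bool sin_weight) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = sample_theta(false, alpha, 0.0, 0.0, env, sin_weight);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_rayleigh(int n, double l, double c2, double env,
                                  bool sin_weight) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = sample_theta(true, 0.0, l, c2, env, sin_weight);
  return out;
}

// deflect d by polar angle th about itself, azimuth ph in a frame built from
// the global axis of smallest |component| of d
static void rotate_dir(double* d, double th, double ph) {
  int k = 0;
  if (std::fabs(d[1]) < std::fabs(d[k])) k = 1;
  if (std::fabs(d[2]) < std::fabs(d[k])) k = 2;
  double a[3] = {0.0, 0.0, 0.0};
  a[k] = 1.0;
  double e1[3] = {d[1] * a[2] - d[2] * a[1],
                  d[2] * a[0] - d[0] * a[2],
                  d[0] * a[1] - d[1] * a[0]};
  double n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int i = 0; i < 3; ++i) e1[i] /= n;
  double e2[3] = {d[1] * e1[2] - d[2] * e1[1],
                  d[2] * e1[0] - d[0] * e1[2],
                  d[0] * e1[1] - d[1] * e1[0]};
  double st = std::sin(th), ct = std::cos(th);
  double cp = std::cos(ph), sp = std::sin(ph);
  double nd[3];
  for (int i = 0; i < 3; ++i) nd[i] = ct * d[i] + st * (cp * e1[i] + sp * e2[i]);
  double nn = std::sqrt(nd[0] * nd[0] + nd[1] * nd[1] + nd[2] * nd[2]);
  for (int i = 0; i < 3; ++i) d[i] = nd[i] / nn;
}

// [[Rcpp::export]]
NumericVector cpp_rotate_direction(NumericVector direction, double theta,
                                   double phi) {
  double d[3] = {direction[0], direction[1], direction[2]};
  rotate_dir(d, theta, phi);
  return NumericVector::create(d[0], d[1], d[2]);
}

struct Box {
  double lo[3], hi[3];
  bool contains(const double* p) const {
    for (int i = 0; i < 3; ++i)
      if (p[i] < lo[i] || p[i] > hi[i]) return false;
    return true;
  }
  // slab-method ray intersection; returns false on miss
  bool intersect(const double* p, const double* d, double& t0, double& t1) const {
    t0 = -DBL_MAX;
    t1 = DBL_MAX;
    for (int i = 0; i < 3; ++i) {
      if (d[i] == 0.0) {
        if (p[i] < lo[i] || p[i] > hi[i]) return false;
      } else {
        double ta = (lo[i] - p[i]) / d[i];
        double tb = (hi[i] - p[i]) / d[i];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 > t1) return false;
      }
    }
    return true;
  }
};

struct Geometry {
  Box bg;
  int bg_mat;
  std::vector<Box> inc;
  std::vector<int> inc_mat;
  // material index at a point (inclusions override background); -1 = outside
  int mat_at(const double* p) const {
    if (!bg.contains(p)) return -1;
    for (size_t j = 0; j < inc.size(); ++j)
      if (inc[j].contains(p)) return inc_mat[j];
    return bg_mat;
  }
};

// Walk from pos along dir consuming optical depth tau.
// Returns true if an interaction occurs (pos, imat updated);
// false if the photon escapes (pos updated to the exit point).
static bool walk(const Geometry& g, const NumericVector& mu_tot, double* pos,
                 const double* dir, double tau, int* imat) {
  double t0, t1;
  if (!g.bg.intersect(pos, dir, t0, t1) || t1 <= 0) return false;
  double t_exit = t1;
  // breakpoints at every box face crossed inside (0, t_exit)
  std::vector<double> ts;
  ts.push_back(0.0);
  ts.push_back(t_exit);
  for (size_t j = 0; j < g.inc.size(); ++j) {
    double a, b;
    if (g.inc[j].intersect(pos, dir, a, b)) {
      if (a > 0 && a < t_exit) ts.push_back(a);
      if (b > 0 && b < t_exit) ts.push_back(b);
    }
  }
  std::sort(ts.begin(), ts.end());
  double cum = 0.0;
  for (size_t k = 0; k + 1 < ts.size(); ++k) {
    double ta = ts[k], tb = ts[k + 1];
    double len = tb - ta;
    if (len <= 0) continue;
    double mid = 0.5 * (ta + tb);
    double pm[3] = {pos[0] + mid * dir[0], pos[1] + mid * dir[1],
                    pos[2] + mid * dir[2]};
    int m = g.mat_at(pm);
    double mu = (m >= 0) ? mu_tot[m] : 0.0;
    double seg = mu * len;
    if (cum + seg >= tau && mu > 0) {
      double s = ta + (tau - cum) / mu;
      for (int i = 0; i < 3; ++i) pos[i] += s * dir[i];
      *imat = m;
      return true;
    }
    cum += seg;
  }
  for (int i = 0; i < 3; ++i) pos[i] += t_exit * dir[i];
  return false;
}

// Collimated-cell acceptance kernels for the single-scattering model,
// estimated by Monte Carlo over the exact grid geometry: photons scattered
// at height R above the detector plane, at source offsets (sx, sy) uniform
// within a cell (units of pitch), with polar angles th and azimuths phi,
// are traced to the detector; a photon is accepted iff it passes the
// angular gate (tan(th) <= tan_gate) and stays within one grid cell over
// the collimator height H. Returns, per depth, the (2*kmax+1)^2 matrix of
// acceptance counts by landing-cell offset.
// [[Rcpp::export]]
NumericVector cpp_collimator_kernel(NumericVector tanth, NumericVector cosphi,
                                    NumericVector sinphi,
                                    NumericVector sx, NumericVector sy,
                                    NumericVector R_vec, double H,
                                    double pitch, double tan_gate, int kmax) {
  int n = tanth.size(), nd = R_vec.size(), w = 2 * kmax + 1;
  NumericVector out(w * w * nd);
  for (int iz = 0; iz < nd; ++iz) {
    double a = R_vec[iz] / pitch;
    double b = (R_vec[iz] - H) / pitch;
    double* slice = &out[w * w * iz];
    for (int i = 0; i < n; ++i) {
      if (tanth[i] > tan_gate) continue;
      double dxu = tanth[i] * cosphi[i];
      double dyu = tanth[i] * sinphi[i];
      double px = sx[i] + a * dxu, py = sy[i] + a * dyu;
      double qx = sx[i] + b * dxu, qy = sy[i] + b * dyu;
      int du = (int)std::floor(px), dv = (int)std::floor(py);
      if ((int)std::floor(qx) != du || (int)std::floor(qy) != dv) continue;
      if (du < -kmax || du > kmax || dv < -kmax || dv > kmax) continue;
      slice[(du + kmax) + w * (dv + kmax)] += 1.0;
    }
  }
  return out;
}

// Full transport run: parallel beam along +z over the background's lateral
// extent, entering at the background's low-z face. Escaping photons are
// offered to every detector configuration (collimator half-angle + plane).
// Uses R's global RNG: seed with set.seed() before calling.
// [[Rcpp::export]]
List cpp_simulate(double n_photons,
                  NumericVector bg_lo, NumericVector bg_hi, int bg_mat,
                  NumericMatrix inc_lo, NumericMatrix inc_hi,
                  IntegerVector inc_mat,
                  NumericVector mu_t, NumericVector mu_s, NumericVector beta,
                  double alpha, double env_c,
                  double ray_l, double ray_c2, double env_r,
                  bool sin_weight,
                  NumericVector det_cos_half, NumericVector det_plane_z,
                  IntegerVector det_nu, IntegerVector det_nv,
                  NumericVector det_pitch,
                  NumericVector det_cx, NumericVector det_cy,
                  NumericVector det_H,
                  int max_events) {
  Geometry g;
  for (int i = 0; i < 3; ++i) { g.bg.lo[i] = bg_lo[i]; g.bg.hi[i] = bg_hi[i]; }
  g.bg_mat = bg_mat;
  int ninc = inc_lo.nrow();
  for (int j = 0; j < ninc; ++j) {
    Box b;
    for (int i = 0; i < 3; ++i) { b.lo[i] = inc_lo(j, i); b.hi[i] = inc_hi(j, i); }
    g.inc.push_back(b);
    g.inc_mat.push_back(inc_mat[j]);
  }
  int nmat = mu_t.size();
  NumericVector mu_tot(nmat);
  for (int m = 0; m < nmat; ++m) mu_tot[m] = mu_t[m] + mu_s[m];

  int K = det_cos_half.size();
  std::vector<NumericVector> imgs;
  for (int k = 0; k < K; ++k) {
    NumericVector img(det_nu[k] * det_nv[k] * 3);
    imgs.push_back(img);
  }
  NumericMatrix detected(K, 3);
  NumericVector detected_single(K); // accepted photons with exactly 1 scatter
  NumericVector escaped_by_class(3);
  double n_absorbed = 0, n_escaped = 0, n_capped = 0;

  double sx = g.bg.hi[0] - g.bg.lo[0];
  double sy = g.bg.hi[1] - g.bg.lo[1];
  long long N = (long long)n_photons;

  for (long long i = 0; i < N; ++i) {
    double pos[3] = {g.bg.lo[0] + sx * u01(), g.bg.lo[1] + sy * u01(),
                     g.bg.lo[2]};
    double dir[3] = {0.0, 0.0, 1.0};
    int nR = 0, nC = 0;
    bool alive = true;
    int events = 0;
    while (alive) {
      double tau = -std::log(xi01());
      int m = -1;
      if (!walk(g, mu_tot, pos, dir, tau, &m)) {
        // escaped
        n_escaped += 1;
        int cls = (nR == 0 && nC == 0) ? 0 : (nC == 0 ? 1 : 2);
        escaped_by_class[cls] += 1;
        if (dir[2] > 0) {
          for (int k = 0; k < K; ++k) {
            if (dir[2] < det_cos_half[k]) continue;
            double t = (det_plane_z[k] - pos[2]) / dir[2];
            double px = pos[0] + t * dir[0];
            double py = pos[1] + t * dir[1];
            double half_u = 0.5 * det_nu[k] * det_pitch[k];
            double half_v = 0.5 * det_nv[k] * det_pitch[k];
            int iu = (int)std::floor((px - (det_cx[k] - half_u)) / det_pitch[k]);
            int iv = (int)std::floor((py - (det_cy[k] - half_v)) / det_pitch[k]);
            if (det_H[k] > 0) {
              // septal cell confinement: the photon must stay inside one
              // grid cell over the collimator height H, else a septum
              // absorbs it
              double qx = px - det_H[k] * dir[0] / dir[2];
              double qy = py - det_H[k] * dir[1] / dir[2];
              int ju = (int)std::floor((qx - (det_cx[k] - half_u)) / det_pitch[k]);
              int jv = (int)std::floor((qy - (det_cy[k] - half_v)) / det_pitch[k]);
              if (ju != iu || jv != iv) continue;
            }
            if (iu >= 0 && iu < det_nu[k] && iv >= 0 && iv < det_nv[k]) {
              imgs[k][iu + det_nu[k] * (iv + det_nv[k] * cls)] += 1;
              detected(k, cls) += 1;
              if (nR + nC == 1) detected_single[k] += 1;
            }
          }
        }
        alive = false;
      } else {
        // interaction in material m
        double pa = mu_t[m] / mu_tot[m];
        if (u01() < pa) {
          n_absorbed += 1;
          alive = false;
        } else {
          bool rayleigh = (u01() < beta[m]);
          double th = rayleigh
                          ? sample_theta(true, 0.0, ray_l, ray_c2, env_r, sin_weight)
                          : sample_theta(false, alpha, 0.0, 0.0, env_c, sin_weight);
          double ph = 2.0 * PI_ * u01();
          rotate_dir(dir, th, ph);
          if (rayleigh) ++nR; else ++nC;
          if (++events >= max_events) {
            n_absorbed += 1;
            n_capped += 1;
            alive = false;
          }
        }
      }
    }
  }

  List out_imgs(K);
  for (int k = 0; k < K; ++k) {
    imgs[k].attr("dim") = IntegerVector::create(det_nu[k], det_nv[k], 3);
    out_imgs[k] = imgs[k];
  }
  return List::create(_["images"] = out_imgs,
                      _["launched"] = (double)N,
                      _["absorbed"] = n_absorbed,
                      _["capped"] = n_capped,
                      _["escaped"] = n_escaped,
                      _["escaped_by_class"] = escaped_by_class,
                      _["detected"] = detected,
                      _["detected_single"] = detected_single);
}
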