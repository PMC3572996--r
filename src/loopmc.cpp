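// Compiled kernels for the base-pair-step Monte Carlo: Gaussian chain
// generation, HU footprint placement, direct and half-chain ensemble
// sampling, and bending-correlation accumulation.  All angles are radians
// and all lengths Angstroms inside this file; R wrappers convert.
//
// Randomness comes from R's own generator (norm_rand / unif_rand), so a
// set.seed() on the R side makes every run bit-for-bit reproducible.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

struct Frame {
  double R[9];  // row-major rotation
  double r[3];  // displacement
};

inline void set_identity(Frame &f) {
  for (int i = 0; i < 9; ++i) f.R[i] = 0.0;
  f.R[0] = f.R[4] = f.R[8] = 1.0;
  f.r[0] = f.r[1] = f.r[2] = 0.0;
}

// a <- a * b (compose on the right)
inline void compose(Frame &a, const Frame &b) {
  double R[9], r[3];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) {
      R[3 * i + j] = a.R[3 * i] * b.R[j] + a.R[3 * i + 1] * b.R[3 + j] +
                     a.R[3 * i + 2] * b.R[6 + j];
    }
    r[i] = a.R[3 * i] * b.r[0] + a.R[3 * i + 1] * b.r[1] +
           a.R[3 * i + 2] * b.r[2] + a.r[i];
  }
  for (int i = 0; i < 9; ++i) a.R[i] = R[i];
  for (int i = 0; i < 3; ++i) a.r[i] = r[i];
}

inline void invert(const Frame &a, Frame &out) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out.R[3 * i + j] = a.R[3 * j + i];
  for (int i = 0; i < 3; ++i)
    out.r[i] = -(out.R[3 * i] * a.r[0] + out.R[3 * i + 1] * a.r[1] +
                 out.R[3 * i + 2] * a.r[2]);
}

// Mid-step-frame generator matrix from (tilt, roll, twist, shift, slide,
// rise); matches params_to_transform() on the R side.
inline void par2frame(const double th[6], Frame &f) {
  const double tl = th[0], ro = th[1], tw = th[2];
  const double gam = std::sqrt(tl * tl + ro * ro);
  const double phi = (gam > 0.0) ? std::atan2(tl, ro) : 0.0;
  const double a = tw / 2 - phi, b = tw / 2 + phi;
  const double ca = std::cos(a), sa = std::sin(a);
  const double cb = std::cos(b), sb = std::sin(b);
  const double cg = std::cos(gam), sg = std::sin(gam);
  // R = Rz(a) Ry(gam) Rz(b)
  f.R[0] = ca * cg * cb - sa * sb;
  f.R[1] = -ca * cg * sb - sa * cb;
  f.R[2] = ca * sg;
  f.R[3] = sa * cg * cb + ca * sb;
  f.R[4] = -sa * cg * sb + ca * cb;
  f.R[5] = sa * sg;
  f.R[6] = -sg * cb;
  f.R[7] = sg * sb;
  f.R[8] = cg;
  // Tm = Rz(a) Ry(gam/2) Rz(phi); r = Tm (shift, slide, rise)
  const double ch = std::cos(gam / 2), sh = std::sin(gam / 2);
  const double cp = std::cos(phi), sp = std::sin(phi);
  double Tm[9];
  Tm[0] = ca * ch * cp - sa * sp;
  Tm[1] = -ca * ch * sp - sa * cp;
  Tm[2] = ca * sh;
  Tm[3] = sa * ch * cp + ca * sp;
  Tm[4] = -sa * ch * sp + ca * cp;
  Tm[5] = sa * sh;
  Tm[6] = -sh * cp;
  Tm[7] = sh * sp;
  Tm[8] = ch;
  for (int i = 0; i < 3; ++i)
    f.r[i] = Tm[3 * i] * th[3] + Tm[3 * i + 1] * th[4] + Tm[3 * i + 2] * th[5];
}

struct Metrics {
  double r_norm, cos_g, cos_f, phi;
};

inline void end_metrics(const Frame &f, Metrics &m) {
  m.r_norm = std::sqrt(f.r[0] * f.r[0] + f.r[1] * f.r[1] + f.r[2] * f.r[2]);
  double cg = f.R[8];
  if (cg > 1.0) cg = 1.0;
  if (cg < -1.0) cg = -1.0;
  m.cos_g = cg;
  // factor the bend out as a single rotation about e_z x z'
  const double zx = f.R[2], zy = f.R[5];
  const double s = std::sqrt(zx * zx + zy * zy);
  double t00, t11, t10, t01;
  if (s < 1e-12) {
    t00 = f.R[0]; t11 = f.R[4]; t10 = f.R[3]; t01 = f.R[1];
  } else {
    const double ax = -zy / s, ay = zx / s;  // unit bend axis (in plane)
    const double gam = std::acos(cg);
    const double sg = std::sin(gam), vg = 1.0 - cg;
    double Rb[9];
    Rb[0] = 1 + vg * (ax * ax - 1);
    Rb[1] = vg * ax * ay;
    Rb[2] = sg * ay;
    Rb[3] = vg * ax * ay;
    Rb[4] = 1 + vg * (ay * ay - 1);
    Rb[5] = -sg * ax;
    Rb[6] = -sg * ay;
    Rb[7] = sg * ax;
    Rb[8] = cg;
    // Rtw = Rb^T * R; only need the upper-left 2x2
    t00 = Rb[0] * f.R[0] + Rb[3] * f.R[3] + Rb[6] * f.R[6];
    t01 = Rb[0] * f.R[1] + Rb[3] * f.R[4] + Rb[6] * f.R[7];
    t10 = Rb[1] * f.R[0] + Rb[4] * f.R[3] + Rb[7] * f.R[6];
    t11 = Rb[1] * f.R[1] + Rb[4] * f.R[4] + Rb[7] * f.R[7];
  }
  m.phi = std::atan2(t10 - t01, t00 + t11);
  m.cos_f = std::cos(m.phi);
}

inline Frame frame_from_matrix(const NumericMatrix &M) {
  Frame f;
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) f.R[3 * i + j] = M(i, j);
    f.r[i] = M(i, 3);
  }
  return f;
}

struct Templates {
  // 14 x 6 step parameters per variant, flattened
  std::vector<std::vector<double>> steps;
  int footprint;
  bool empty() const { return steps.empty(); }
};

Templates templates_from_list(List hu) {
  Templates t;
  t.footprint = 14;
  for (int v = 0; v < hu.size(); ++v) {
    NumericMatrix m = hu[v];
    t.footprint = m.nrow();
    std::vector<double> s(m.nrow() * 6);
    for (int i = 0; i < m.nrow(); ++i)
      for (int j = 0; j < 6; ++j) s[6 * i + j] = m(i, j);
    t.steps.push_back(s);
  }
  return t;
}

// Scan-and-place HU occupancy on a window of n steps; returns starts
// (0-based) and variants, and advances the chain frame A through the window
// (Gaussian steps where free, template steps where occupied).
inline void sample_window(Frame &A, int n, const double sig[3],
                          const double intr[6], const Templates &hu,
                          double p, std::vector<int> *starts,
                          std::vector<int> *variants) {
  double th[6];
  th[3] = intr[3]; th[4] = intr[4]; th[5] = intr[5];
  const int f = hu.footprint;
  int i = 0;
  while (i < n) {
    bool placed = false;
    if (!hu.empty() && p > 0.0 && i <= n - f && unif_rand() < p) {
      int v = (int)(unif_rand() * hu.steps.size());
      if (v >= (int)hu.steps.size()) v = (int)hu.steps.size() - 1;
      const std::vector<double> &tp = hu.steps[v];
      Frame g;
      for (int k = 0; k < f; ++k) {
        par2frame(&tp[6 * k], g);
        compose(A, g);
      }
      if (starts) starts->push_back(i);
      if (variants) variants->push_back(v);
      i += f;
      placed = true;
    }
    if (!placed) {
      th[0] = intr[0] + sig[0] * norm_rand();
      th[1] = intr[1] + sig[1] * norm_rand();
      th[2] = intr[2] + sig[2] * norm_rand();
      Frame g;
      par2frame(th, g);
      compose(A, g);
      ++i;
    }
  }
}

inline void gaussian_step(Frame &A, const double sig[3], const double intr[6]) {
  double th[6];
  th[0] = intr[0] + sig[0] * norm_rand();
  th[1] = intr[1] + sig[1] * norm_rand();
  th[2] = intr[2] + sig[2] * norm_rand();
  th[3] = intr[3]; th[4] = intr[4]; th[5] = intr[5];
  Frame g;
  par2frame(th, g);
  compose(A, g);
}

inline double deviation(const Metrics &m, double r_max, double cgm,
                        double cfm) {
  return m.r_norm / r_max + (1.0 - m.cos_g) / (1.0 - cgm) +
         (1.0 - m.cos_f) / (1.0 - cfm);
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_steps_to_frames(NumericMatrix steps) {
  // Returns (n+1) x 12 matrix: rows = base-pair frames (R row-major, then r)
  int n = steps.nrow();
  NumericMatrix out(n + 1, 12);
  Frame A;
  set_identity(A);
  auto fill = [&](int row) {
    for (int k = 0; k < 9; ++k) out(row, k) = A.R[k];
    for (int k = 0; k < 3; ++k) out(row, 9 + k) = A.r[k];
  };
  fill(0);
  double th[6];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 6; ++j) th[j] = steps(i, j);
    Frame g;
    par2frame(th, g);
    compose(A, g);
    fill(i + 1);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bend_correlation(int n_chains, int n_steps,
                                   NumericVector sigma, NumericVector intrinsic,
                                   int kmax) {
  // Mean cosine of the angle between base-pair normals separated by k steps,
  // averaged over positions and chains, for k = 1..kmax.
  std::vector<double> acc(kmax, 0.0);
  std::vector<double> cnt(kmax, 0.0);
  std::vector<double> zx(n_steps + 1), zy(n_steps + 1), zz(n_steps + 1);
  double sig[3] = {sigma[0], sigma[1], sigma[2]};
  double intr[6];
  for (int j = 0; j < 6; ++j) intr[j] = intrinsic[j];
  for (int c = 0; c < n_chains; ++c) {
    Frame A;
    set_identity(A);
    zx[0] = 0; zy[0] = 0; zz[0] = 1;
    for (int i = 0; i < n_steps; ++i) {
      gaussian_step(A, sig, intr);
      zx[i + 1] = A.R[2];
      zy[i + 1] = A.R[5];
      zz[i + 1] = A.R[8];
    }
    for (int k = 1; k <= kmax; ++k) {
      double s = 0.0;
      for (int i = 0; i + k <= n_steps; ++i)
        s += zx[i] * zx[i + k] + zy[i] * zy[i + k] + zz[i] * zz[i + k];
      acc[k - 1] += s;
      cnt[k - 1] += n_steps - k + 1;
    }
  }
  NumericVector out(kmax);
  for (int k = 0; k < kmax; ++k) out[k] = acc[k] / cnt[k];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_place_counts(int n, double p, int footprint, int n_draws,
                               IntegerVector dummy_variants) {
  // Occupancy counts of the scan-and-place process on a bare window, used
  // for calibration checks and the enumeration oracle.
  IntegerVector out(n_draws);
  for (int d = 0; d < n_draws; ++d) {
    int i = 0, c = 0;
    while (i < n) {
      if (i <= n - footprint && unif_rand() < p) {
        c++;
        i += footprint;
      } else {
        ++i;
      }
    }
    out[d] = c;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_direct_ensemble(NumericMatrix prefix, NumericMatrix suffix,
                         int n1, int n2, NumericVector sigma,
                         NumericVector intrinsic, List hu_templates,
                         double p1, double p2, List cond_transforms,
                         double r_max, double cos_g_min, double cos_f_min,
                         double n_trials_d, bool gaussian_join) {
  const int n_trials = (int)n_trials_d;
  Frame pre = frame_from_matrix(prefix);
  Frame suf = frame_from_matrix(suffix);
  Templates hu = templates_from_list(hu_templates);
  double sig[3] = {sigma[0], sigma[1], sigma[2]};
  double intr[6];
  for (int j = 0; j < 6; ++j) intr[j] = intrinsic[j];
  const int ncond = cond_transforms.size();
  std::vector<Frame> conds(ncond);
  for (int c = 0; c < ncond; ++c)
    conds[c] = frame_from_matrix(as<NumericMatrix>(cond_transforms[c]));

  std::vector<int> rec_trial, rec_cond, rec_hu, rec_mult;
  std::vector<double> rec_r, rec_cg, rec_cf, rec_phi, rec_dev;
  List rec_starts;
  std::vector<std::vector<int>> keep_starts, keep_vars;

  std::vector<int> starts, vars;
  for (int t = 0; t < n_trials; ++t) {
    starts.clear();
    vars.clear();
    Frame A = pre;
    sample_window(A, n1, sig, intr, hu, p1, &starts, &vars);
    int off = starts.size();
    sample_window(A, n2, sig, intr, hu, p2, &starts, &vars);
    for (size_t k = off; k < starts.size(); ++k) starts[k] += n1;
    compose(A, suf);
    if (gaussian_join) gaussian_step(A, sig, intr);
    int best = -1, mult = 0;
    Metrics bm;
    double bdev = 0.0;
    for (int c = 0; c < ncond; ++c) {
      // cheap position reject before the full rotation product
      const Frame &J = conds[c];
      double rx = A.R[0] * J.r[0] + A.R[1] * J.r[1] + A.R[2] * J.r[2] + A.r[0];
      double ry = A.R[3] * J.r[0] + A.R[4] * J.r[1] + A.R[5] * J.r[2] + A.r[1];
      double rz = A.R[6] * J.r[0] + A.R[7] * J.r[1] + A.R[8] * J.r[2] + A.r[2];
      if (rx * rx + ry * ry + rz * rz > r_max * r_max) continue;
      Frame M = A;
      compose(M, J);
      Metrics m;
      end_metrics(M, m);
      if (m.r_norm < r_max && m.cos_g >= cos_g_min && m.cos_f >= cos_f_min) {
        double dev = deviation(m, r_max, cos_g_min, cos_f_min);
        ++mult;
        if (best < 0 || dev < bdev) {
          best = c;
          bdev = dev;
          bm = m;
        }
      }
    }
    if (best >= 0) {
      rec_trial.push_back(t + 1);
      rec_cond.push_back(best + 1);
      rec_hu.push_back((int)starts.size());
      rec_mult.push_back(mult);
      rec_r.push_back(bm.r_norm);
      rec_cg.push_back(bm.cos_g);
      rec_cf.push_back(bm.cos_f);
      rec_phi.push_back(bm.phi);
      rec_dev.push_back(bdev);
      keep_starts.push_back(starts);
      keep_vars.push_back(vars);
    }
    if ((t & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  int na = rec_trial.size();
  List pl(na), vl(na);
  for (int i = 0; i < na; ++i) {
    pl[i] = IntegerVector(keep_starts[i].begin(), keep_starts[i].end());
    vl[i] = IntegerVector(keep_vars[i].begin(), keep_vars[i].end());
  }
  return List::create(
      _["samples"] = (double)n_trials, _["trial"] = wrap(rec_trial),
      _["cond"] = wrap(rec_cond), _["hu_count"] = wrap(rec_hu),
      _["multiplicity"] = wrap(rec_mult), _["r"] = wrap(rec_r),
      _["cos_gamma"] = wrap(rec_cg), _["cos_phi"] = wrap(rec_cf),
      _["phi"] = wrap(rec_phi), _["dev"] = wrap(rec_dev),
      _["hu_starts"] = pl, _["hu_variants"] = vl);
}

namespace {
inline std::uint64_t cell_key(double x, double y, double z, double h) {
  const std::int64_t ix = (std::int64_t)std::floor(x / h) + (1 << 20);
  const std::int64_t iy = (std::int64_t)std::floor(y / h) + (1 << 20);
  const std::int64_t iz = (std::int64_t)std::floor(z / h) + (1 << 20);
  const std::uint64_t m = (1ull << 21) - 1;
  return ((std::uint64_t)(ix & m) << 42) | ((std::uint64_t)(iy & m) << 21) |
         (std::uint64_t)(iz & m);
}
}  // namespace

// [[Rcpp::export]]
List cpp_halfchain_ensemble(NumericMatrix prefix, NumericMatrix suffix,
                            int n1, int n2, NumericVector sigma,
                            NumericVector intrinsic, List hu_templates,
                            double p1, double p2, List cond_transforms,
                            double r_max, double cos_g_min, double cos_f_min,
                            int n_half, bool gaussian_join) {
  // Half 1 = prefix * window1; half 2 = window2 * suffix (* Gaussian joining
  // step for cyclization).  The M x M pairings are pruned with a spatial
  // hash on the closure position error, which is exactly
  // |b_j - q_i| with b_j = position of (half2 * cond) and q_i = position of
  // half1^{-1}; bins of edge r_max with 27-neighbour queries are
  // conservative, so no accepted pair can be missed.
  Frame pre = frame_from_matrix(prefix);
  Frame suf = frame_from_matrix(suffix);
  Templates hu = templates_from_list(hu_templates);
  double sig[3] = {sigma[0], sigma[1], sigma[2]};
  double intr[6];
  for (int j = 0; j < 6; ++j) intr[j] = intrinsic[j];
  const int ncond = cond_transforms.size();
  std::vector<Frame> conds(ncond);
  for (int c = 0; c < ncond; ++c)
    conds[c] = frame_from_matrix(as<NumericMatrix>(cond_transforms[c]));

  std::vector<Frame> h1(n_half), h2(n_half);
  std::vector<int> hu1(n_half), hu2(n_half);
  std::vector<int> starts, vars;
  for (int i = 0; i < n_half; ++i) {
    starts.clear();
    Frame A = pre;
    sample_window(A, n1, sig, intr, hu, p1, &starts, nullptr);
    h1[i] = A;
    hu1[i] = (int)starts.size();
  }
  for (int j = 0; j < n_half; ++j) {
    starts.clear();
    Frame A;
    set_identity(A);
    sample_window(A, n2, sig, intr, hu, p2, &starts, nullptr);
    compose(A, suf);
    if (gaussian_join) gaussian_step(A, sig, intr);
    h2[j] = A;
    hu2[j] = (int)starts.size();
  }
  // q_i = position of h1^{-1}
  std::vector<double> qx(n_half), qy(n_half), qz(n_half);
  for (int i = 0; i < n_half; ++i) {
    Frame inv;
    invert(h1[i], inv);
    qx[i] = inv.r[0];
    qy[i] = inv.r[1];
    qz[i] = inv.r[2];
  }

  struct Rec {
    int cond;
    Metrics m;
    double dev;
    int mult;
  };
  std::map<std::pair<int, int>, Rec> best;

  std::unordered_map<std::uint64_t, std::vector<int>> grid;
  std::vector<double> bx(n_half), by(n_half), bz(n_half);
  for (int c = 0; c < ncond; ++c) {
    const Frame &J = conds[c];
    grid.clear();
    for (int j = 0; j < n_half; ++j) {
      const Frame &B = h2[j];
      bx[j] = B.R[0] * J.r[0] + B.R[1] * J.r[1] + B.R[2] * J.r[2] + B.r[0];
      by[j] = B.R[3] * J.r[0] + B.R[4] * J.r[1] + B.R[5] * J.r[2] + B.r[1];
      bz[j] = B.R[6] * J.r[0] + B.R[7] * J.r[1] + B.R[8] * J.r[2] + B.r[2];
      grid[cell_key(bx[j], by[j], bz[j], r_max)].push_back(j);
    }
    for (int i = 0; i < n_half; ++i) {
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            auto it = grid.find(cell_key(qx[i] + dx * r_max, qy[i] + dy * r_max,
                                         qz[i] + dz * r_max, r_max));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              const double ex = bx[j] - qx[i], ey = by[j] - qy[i],
                           ez = bz[j] - qz[i];
              if (ex * ex + ey * ey + ez * ez > r_max * r_max) continue;
              Frame M = h1[i];
              compose(M, h2[j]);
              compose(M, conds[c]);
              Metrics m;
              end_metrics(M, m);
              if (m.r_norm < r_max && m.cos_g >= cos_g_min &&
                  m.cos_f >= cos_f_min) {
                double dev = deviation(m, r_max, cos_g_min, cos_f_min);
                auto key = std::make_pair(i, j);
                auto f = best.find(key);
                if (f == best.end()) {
                  best[key] = Rec{c, m, dev, 1};
                } else {
                  f->second.mult++;
                  if (dev < f->second.dev) {
                    f->second.cond = c;
                    f->second.m = m;
                    f->second.dev = dev;
                  }
                }
              }
            }
          }
      if ((i & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    }
  }
  const int na = (int)best.size();
  IntegerVector ri(na), rj(na), rc(na), rh(na), rm(na);
  NumericVector rr(na), rcg(na), rcf(na), rphi(na), rdev(na);
  int k = 0;
  for (auto &kv : best) {
    ri[k] = kv.first.first + 1;
    rj[k] = kv.first.second + 1;
    rc[k] = kv.second.cond + 1;
    rh[k] = hu1[kv.first.first] + hu2[kv.first.second];
    rm[k] = kv.second.mult;
    rr[k] = kv.second.m.r_norm;
    rcg[k] = kv.second.m.cos_g;
    rcf[k] = kv.second.m.cos_f;
    rphi[k] = kv.second.m.phi;
    rdev[k] = kv.second.dev;
    ++k;
  }
  return List::create(
      _["samples"] = (double)n_half * (double)n_half, _["n_half"] = n_half,
      _["i"] = ri, _["j"] = rj, _["cond"] = rc, _["hu_count"] = rh,
      _["multiplicity"] = rm, _["r"] = rr, _["cos_gamma"] = rcg,
      _["cos_phi"] = rcf, _["phi"] = rphi, _["dev"] = rdev);
}
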