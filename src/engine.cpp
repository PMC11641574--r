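// Hybrid MD core: velocity-Verlet integration of the bead-spring motor and
// point solvent, WCA motor-solvent forces via a bead cell list with the
// minimum-image convention, and microcanonical surface reactions: a reaction
// is latched on the first inward cutoff crossing and the species flip
// materialises once the particle is outside every bead cutoff, where the
// pair potential is exactly zero for both species.
//
// Conventions: solvent species 0=A, 1=I, 2=B; motor particle class 0=E0,
// 1=E1, 2=E2, 3=internal (no solvent interaction). Motor positions are kept
// unwrapped; solvent positions are wrapped into [0, L).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}
static inline double wrap0(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;   // guard against rounding at the boundary
  if (x < 0) x = 0;
  return x;
}
static inline double wca_pe(double r2, double eps, double sigma) {
  double s2 = sigma * sigma / r2, s6 = s2 * s2 * s2;
  return 4.0 * eps * (s6 * s6 - s6 + 0.25);
}
static inline double wca_f_over_r(double r2, double eps, double sigma) {
  double s2 = sigma * sigma / r2, s6 = s2 * s2 * s2;
  return 24.0 * eps * (2.0 * s6 * s6 - s6) / r2;
}

// xorshift64* for the optional sub-unit reaction probability
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  double unif() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    uint64_t r = s * 0x2545F4914F6CDD1DULL;
    return (r >> 11) * (1.0 / 9007199254740992.0);
  }
};

struct CellList {
  int nx, ny, nz;
  double cx, cy, cz;
  std::vector<int> head, nxt;
  void build(const NumericMatrix& pos, const std::vector<int>& items,
             double rcmax, const double* box) {
    nx = std::max(1, (int)std::floor(box[0] / rcmax));
    ny = std::max(1, (int)std::floor(box[1] / rcmax));
    nz = std::max(1, (int)std::floor(box[2] / rcmax));
    cx = box[0] / nx; cy = box[1] / ny; cz = box[2] / nz;
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(pos.nrow(), -1);
    for (int b : items) {
      int ix = std::min(nx - 1, (int)(wrap0(pos(b, 0), box[0]) / cx));
      int iy = std::min(ny - 1, (int)(wrap0(pos(b, 1), box[1]) / cy));
      int iz = std::min(nz - 1, (int)(wrap0(pos(b, 2), box[2]) / cz));
      int c = ix + nx * (iy + ny * iz);
      nxt[b] = head[c];
      head[c] = b;
    }
  }
  // distinct neighbour cell ids of the cell containing (x,y,z); returns count
  int neighbours(double x, double y, double z, const double* box,
                 int* out) const {
    int ix = std::min(nx - 1, (int)(wrap0(x, box[0]) / cx));
    int iy = std::min(ny - 1, (int)(wrap0(y, box[1]) / cy));
    int iz = std::min(nz - 1, (int)(wrap0(z, box[2]) / cz));
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int jx = (ix + dx + nx) % nx;
          int jy = (iy + dy + ny) % ny;
          int jz = (iz + dz + nz) % nz;
          int c = jx + nx * (jy + ny * jz);
          if (nx < 3 || ny < 3 || nz < 3) {  // small grids can alias cells
            bool dup = false;
            for (int k = 0; k < cnt; ++k) if (out[k] == c) { dup = true; break; }
            if (dup) continue;
          }
          out[cnt++] = c;
        }
    return cnt;
  }
};

struct Engine {
  NumericMatrix mpos, mvel, spos, svel, eps;
  NumericVector mmass, msigma, r0v;
  IntegerVector mclass, sspec, inside1, inside2, pending;
  IntegerMatrix springs;
  double ks, ms, dt;
  double box[3];
  double react_prob;
  bool react_on;
  XRng rng;

  int nm, nsv;
  std::vector<int> beads;            // motor indices with solvent interaction
  double rc2cls[3], rccls[3], sigcls[3], rcmax;
  std::vector<double> fm, fs;        // forces, length 3*n (x,y,z interleaved)
  CellList cl;
  double pe_wca, pe_spring;
  long n_rxn1, n_rxn2;

  Engine(NumericMatrix mpos_, NumericMatrix mvel_, NumericVector mmass_,
         NumericVector msigma_, IntegerVector mclass_, IntegerMatrix springs_,
         NumericVector r0_, double ks_, NumericMatrix spos_,
         NumericMatrix svel_, IntegerVector sspec_, double ms_,
         IntegerVector in1_, IntegerVector in2_, IntegerVector pending_,
         NumericMatrix eps_, NumericVector box_, double dt_, bool react_on_,
         double react_prob_, uint64_t react_seed)
    : mpos(mpos_), mvel(mvel_), spos(spos_), svel(svel_), eps(eps_),
      mmass(mmass_), msigma(msigma_), r0v(r0_), mclass(mclass_),
      sspec(sspec_), inside1(in1_), inside2(in2_), pending(pending_),
      springs(springs_),
      ks(ks_), ms(ms_), dt(dt_), react_prob(react_prob_), react_on(react_on_),
      rng(react_seed) {
    box[0] = box_[0]; box[1] = box_[1]; box[2] = box_[2];
    nm = mpos.nrow(); nsv = spos.nrow();
    rcmax = 0.0;
    double sig1 = 0.0, sig2 = 0.0;
    for (int i = 0; i < nm; ++i) {
      if (mclass[i] <= 2 && msigma[i] > 0) {
        beads.push_back(i);
        if (mclass[i] == 2) sig2 = msigma[i]; else sig1 = msigma[i];
      }
    }
    sigcls[0] = sig1; sigcls[1] = sig1; sigcls[2] = sig2;
    const double rcf = std::pow(2.0, 1.0 / 6.0);
    for (int c = 0; c < 3; ++c) {
      rccls[c] = rcf * sigcls[c];
      rc2cls[c] = rccls[c] * rccls[c];
      if (rccls[c] > rcmax) rcmax = rcf * sigcls[c];
    }
    if (rcmax <= 0) rcmax = 1.0;  // no interacting beads at all
    fm.assign(3 * (size_t)nm, 0.0);
    fs.assign(3 * (size_t)nsv, 0.0);
    n_rxn1 = n_rxn2 = 0;
  }

  void spring_forces() {
    pe_spring = 0.0;
    int nsp = springs.nrow();
    for (int e = 0; e < nsp; ++e) {
      int i = springs(e, 0) - 1, j = springs(e, 1) - 1;
      double dx = mpos(i, 0) - mpos(j, 0);
      double dy = mpos(i, 1) - mpos(j, 1);
      double dz = mpos(i, 2) - mpos(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - r0v[e];
      pe_spring += 0.5 * ks * dr * dr;
      if (r > 0) {
        double f = -ks * dr / r;
        fm[3 * i] += f * dx; fm[3 * i + 1] += f * dy; fm[3 * i + 2] += f * dz;
        fm[3 * j] -= f * dx; fm[3 * j + 1] -= f * dy; fm[3 * j + 2] -= f * dz;
      }
    }
  }

  // one full force evaluation; when do_react, species flips are processed
  // per particle before its forces are accumulated (bead positions are fixed
  // during the pass, so the particle order is immaterial)
  void compute_forces(bool do_react) {
    std::fill(fm.begin(), fm.end(), 0.0);
    std::fill(fs.begin(), fs.end(), 0.0);
    pe_wca = 0.0;
    spring_forces();
    if (beads.empty()) return;
    cl.build(mpos, beads, rcmax, box);
    int cellbuf[27];
    std::vector<std::pair<int, double>> nb;
    nb.reserve(64);
    double rcmax2 = rcmax * rcmax;
    for (int p = 0; p < nsv; ++p) {
      double px = spos(p, 0), py = spos(p, 1), pz = spos(p, 2);
      int ncell = cl.neighbours(px, py, pz, box, cellbuf);
      nb.clear();
      bool in1 = false, in2 = false, in_any = false;
      for (int k = 0; k < ncell; ++k) {
        for (int b = cl.head[cellbuf[k]]; b >= 0; b = cl.nxt[b]) {
          double dx = min_image(px - mpos(b, 0), box[0]);
          double dy = min_image(py - mpos(b, 1), box[1]);
          double dz = min_image(pz - mpos(b, 2), box[2]);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < rcmax2) {
            nb.emplace_back(b, r2);
            int cls = mclass[b];
            if (r2 < rc2cls[cls]) {
              in_any = true;
              if (cls == 1) in1 = true;
              if (cls == 2) in2 = true;
            }
          }
        }
      }
      if (do_react) {
        // the reaction is latched on the first inward cutoff crossing and
        // the species flip materialises once the particle is outside every
        // bead cutoff, where the pair potential is exactly zero for both
        // species: microcanonical to machine precision
        if (pending[p] == 0 && sspec[p] == 0 && in1 && !inside1[p]) {
          if (react_prob >= 1.0 || rng.unif() < react_prob) {
            pending[p] = 1;
            ++n_rxn1;
          }
        }
        if (pending[p] == 0 && sspec[p] == 1 && in2 && !inside2[p]) {
          if (react_prob >= 1.0 || rng.unif() < react_prob) {
            pending[p] = 2;
            ++n_rxn2;
          }
        }
        if (pending[p] != 0 && !in_any) {
          sspec[p] = pending[p];
          pending[p] = 0;
        }
      }
      inside1[p] = in1 ? 1 : 0;
      inside2[p] = in2 ? 1 : 0;
      // WCA forces with the (possibly flipped) species
      int sp = sspec[p];
      for (const auto& pr : nb) {
        int b = pr.first, cls = mclass[b];
        if (pr.second >= rc2cls[cls]) continue;
        double e = eps(sp, cls);
        pe_wca += wca_pe(pr.second, e, sigcls[cls]);
        double fr = wca_f_over_r(pr.second, e, sigcls[cls]);
        double dx = min_image(px - mpos(b, 0), box[0]);
        double dy = min_image(py - mpos(b, 1), box[1]);
        double dz = min_image(pz - mpos(b, 2), box[2]);
        fs[3 * p] += fr * dx; fs[3 * p + 1] += fr * dy; fs[3 * p + 2] += fr * dz;
        fm[3 * b] -= fr * dx; fm[3 * b + 1] -= fr * dy; fm[3 * b + 2] -= fr * dz;
      }
    }
  }

  double kinetic_energy() const {
    double ke = 0.0;
    for (int i = 0; i < nm; ++i)
      ke += 0.5 * mmass[i] * (mvel(i, 0) * mvel(i, 0) +
                              mvel(i, 1) * mvel(i, 1) +
                              mvel(i, 2) * mvel(i, 2));
    for (int p = 0; p < nsv; ++p)
      ke += 0.5 * ms * (svel(p, 0) * svel(p, 0) + svel(p, 1) * svel(p, 1) +
                        svel(p, 2) * svel(p, 2));
    return ke;
  }

  void momentum(double* out) const {
    out[0] = out[1] = out[2] = 0.0;
    for (int i = 0; i < nm; ++i)
      for (int d = 0; d < 3; ++d) out[d] += mmass[i] * mvel(i, d);
    for (int p = 0; p < nsv; ++p)
      for (int d = 0; d < 3; ++d) out[d] += ms * svel(p, d);
  }

  void check_finite() const {
    for (int i = 0; i < nm; ++i)
      for (int d = 0; d < 3; ++d)
        if (!std::isfinite(mvel(i, d)) || !std::isfinite(mpos(i, d)))
          stop("numerical blow-up at motor particle %d", i + 1);
    for (int p = 0; p < nsv; ++p)
      for (int d = 0; d < 3; ++d)
        if (!std::isfinite(svel(p, d)) || !std::isfinite(spos(p, d)))
          stop("numerical blow-up at solvent particle %d", p + 1);
  }

  // velocity-Verlet steps with per-step reaction handling
  NumericMatrix run(int nsteps, int log_every) {
    compute_forces(false);
    int nlog = (log_every > 0) ? nsteps / log_every : 0;
    NumericMatrix elog(nlog, 7);
    int li = 0;
    for (int s = 1; s <= nsteps; ++s) {
      for (int i = 0; i < nm; ++i) {
        double h = 0.5 * dt / mmass[i];
        mvel(i, 0) += h * fm[3 * i];
        mvel(i, 1) += h * fm[3 * i + 1];
        mvel(i, 2) += h * fm[3 * i + 2];
        mpos(i, 0) += dt * mvel(i, 0);
        mpos(i, 1) += dt * mvel(i, 1);
        mpos(i, 2) += dt * mvel(i, 2);
      }
      double hs = 0.5 * dt / ms;
      for (int p = 0; p < nsv; ++p) {
        svel(p, 0) += hs * fs[3 * p];
        svel(p, 1) += hs * fs[3 * p + 1];
        svel(p, 2) += hs * fs[3 * p + 2];
        spos(p, 0) = wrap0(spos(p, 0) + dt * svel(p, 0), box[0]);
        spos(p, 1) = wrap0(spos(p, 1) + dt * svel(p, 1), box[1]);
        spos(p, 2) = wrap0(spos(p, 2) + dt * svel(p, 2), box[2]);
      }
      compute_forces(react_on);
      for (int i = 0; i < nm; ++i) {
        double h = 0.5 * dt / mmass[i];
        mvel(i, 0) += h * fm[3 * i];
        mvel(i, 1) += h * fm[3 * i + 1];
        mvel(i, 2) += h * fm[3 * i + 2];
      }
      for (int p = 0; p < nsv; ++p) {
        svel(p, 0) += hs * fs[3 * p];
        svel(p, 1) += hs * fs[3 * p + 1];
        svel(p, 2) += hs * fs[3 * p + 2];
      }
      if (log_every > 0 && s % log_every == 0 && li < nlog) {
        double pvec[3];
        momentum(pvec);
        elog(li, 0) = s;
        elog(li, 1) = kinetic_energy();
        elog(li, 2) = pe_wca;
        elog(li, 3) = pe_spring;
        elog(li, 4) = pvec[0]; elog(li, 5) = pvec[1]; elog(li, 6) = pvec[2];
        ++li;
      }
    }
    check_finite();
    return elog;
  }
};

// [[Rcpp::export]]
List ecr_md_cycle_cpp(NumericMatrix mpos, NumericMatrix mvel,
                      NumericVector mmass, NumericVector msigma,
                      IntegerVector mclass, IntegerMatrix springs,
                      NumericVector r0, double ks,
                      NumericMatrix spos, NumericMatrix svel,
                      IntegerVector sspec, double ms,
                      IntegerVector inside1, IntegerVector inside2,
                      IntegerVector pending,
                      NumericMatrix eps, NumericVector box,
                      double dt, int nsteps, bool react, double react_prob,
                      double react_seed, int log_every) {
  NumericMatrix mp = clone(mpos), mv = clone(mvel);
  NumericMatrix sp = clone(spos), sv = clone(svel);
  IntegerVector ss = clone(sspec), i1 = clone(inside1), i2 = clone(inside2);
  IntegerVector pd = clone(pending);
  Engine eng(mp, mv, mmass, msigma, mclass, springs, r0, ks, sp, sv, ss, ms,
             i1, i2, pd, eps, box, dt, react, react_prob,
             (uint64_t)react_seed);
  NumericMatrix elog = eng.run(nsteps, log_every);
  return List::create(
    _["mpos"] = mp, _["mvel"] = mv, _["spos"] = sp, _["svel"] = sv,
    _["sspec"] = ss, _["inside1"] = i1, _["inside2"] = i2, _["pending"] = pd,
    _["n_rxn1"] = (double)eng.n_rxn1, _["n_rxn2"] = (double)eng.n_rxn2,
    _["pe"] = eng.pe_wca + eng.pe_spring, _["ke"] = eng.kinetic_energy(),
    _["elog"] = elog);
}

// [[Rcpp::export]]
List ecr_forces_cpp(NumericMatrix mpos, NumericVector mmass,
                    NumericVector msigma, IntegerVector mclass,
                    IntegerMatrix springs, NumericVector r0, double ks,
                    NumericMatrix spos, IntegerVector sspec,
                    NumericMatrix eps, NumericVector box) {
  NumericMatrix mv(mpos.nrow(), 3), sv(spos.nrow(), 3);
  IntegerVector ss = clone(sspec);
  IntegerVector i1(spos.nrow()), i2(spos.nrow());
  NumericMatrix sp = clone(spos);
  NumericMatrix mp = clone(mpos);
  IntegerVector pd(spos.nrow());
  Engine eng(mp, mv, mmass, msigma, mclass, springs, r0, ks, sp, sv, ss, 1.0,
             i1, i2, pd, eps, box, 0.0, false, 1.0, 1);
  eng.compute_forces(false);
  NumericMatrix fmo(mpos.nrow(), 3), fso(spos.nrow(), 3);
  for (int i = 0; i < mpos.nrow(); ++i)
    for (int d = 0; d < 3; ++d) fmo(i, d) = eng.fm[3 * i + d];
  for (int p = 0; p < spos.nrow(); ++p)
    for (int d = 0; d < 3; ++d) fso(p, d) = eng.fs[3 * p + d];
  return List::create(
    _["f_motor"] = fmo, _["f_solvent"] = fso,
    _["pe_wca"] = eng.pe_wca, _["pe_spring"] = eng.pe_spring,
    _["inside1"] = i1, _["inside2"] = i2);
}

// [[Rcpp::export]]
List ecr_surface_reaction_cpp(NumericMatrix mpos, NumericMatrix mvel,
                              NumericVector mmass, NumericVector msigma,
                              IntegerVector mclass, IntegerMatrix springs,
                              NumericVector r0, double ks,
                              NumericMatrix spos, NumericMatrix svel,
                              IntegerVector sspec, double ms,
                              IntegerVector inside1, IntegerVector inside2,
                              IntegerVector pending,
                              NumericMatrix eps, NumericVector box,
                              double react_prob, double react_seed) {
  NumericMatrix mp = clone(mpos), mv = clone(mvel);
  NumericMatrix sp = clone(spos), sv = clone(svel);
  IntegerVector ss = clone(sspec), i1 = clone(inside1), i2 = clone(inside2);
  IntegerVector pd = clone(pending);
  Engine eng(mp, mv, mmass, msigma, mclass, springs, r0, ks, sp, sv, ss, ms,
             i1, i2, pd, eps, box, 0.0, true, react_prob, (uint64_t)react_seed);
  eng.compute_forces(true);
  return List::create(
    _["mvel"] = mv, _["svel"] = sv, _["sspec"] = ss,
    _["inside1"] = i1, _["inside2"] = i2, _["pending"] = pd,
    _["n_rxn1"] = (double)eng.n_rxn1, _["n_rxn2"] = (double)eng.n_rxn2);
}
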