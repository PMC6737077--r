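#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic RNG (splitmix64 -> xoshiro256++, Box-Muller normals) so a
// trajectory is bit-reproducible from its seed independent of the C++
// standard library implementation.
namespace {

struct Xoshiro {
  uint64_t s[4];
  bool haveSpare = false;
  double spare = 0.0;
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {
    if (haveSpare) { haveSpare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double m = std::sqrt(-2.0 * std::log(u1));
    spare = m * std::sin(2.0 * M_PI * u2);
    haveSpare = true;
    return m * std::cos(2.0 * M_PI * u2);
  }
};

const double ACC_CONV = 4.184e-4;  // a[A/fs^2] = ACC_CONV * F[kcal/mol/A]/m[amu]
const double K_COULOMB = 332.0636;

// Ligand internal + ligand-receptor local forces, written into F (n x 3,
// flat). Returns max |F| component magnitude encountered.
double localForcesImpl(const double *x, int n,
                       const IntegerMatrix &bonds, const NumericVector &bondR0,
                       const NumericVector &bondK,
                       const IntegerMatrix &angles, const NumericVector &angT0,
                       const NumericVector &angK,
                       const NumericMatrix &rx, const NumericVector &rq,
                       const NumericVector &rrad,
                       const NumericVector &lq, const NumericVector &lrad,
                       const NumericVector &rborn, const NumericVector &lborn,
                       double wcaEps, bool localElec, double elecCutoff,
                       double epsSolvent,
                       double tetherK, const NumericVector &tetherC,
                       double *F) {
  for (int i = 0; i < 3 * n; ++i) F[i] = 0.0;
  // harmonic bonds: E = (k/2)(r - r0)^2
  for (int b = 0; b < bonds.nrow(); ++b) {
    const int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double d[3], r2 = 0;
    for (int c = 0; c < 3; ++c) { d[c] = x[3*i+c] - x[3*j+c]; r2 += d[c]*d[c]; }
    const double r = std::sqrt(r2);
    const double fmag = -bondK[b] * (r - bondR0[b]) / r;
    for (int c = 0; c < 3; ++c) { F[3*i+c] += fmag * d[c]; F[3*j+c] -= fmag * d[c]; }
  }
  // harmonic angles: E = (k/2)(theta - theta0)^2
  for (int a = 0; a < angles.nrow(); ++a) {
    const int i = angles(a, 0) - 1, j = angles(a, 1) - 1, k = angles(a, 2) - 1;
    double rij[3], rkj[3], nij = 0, nkj = 0, dot = 0;
    for (int c = 0; c < 3; ++c) {
      rij[c] = x[3*i+c] - x[3*j+c]; rkj[c] = x[3*k+c] - x[3*j+c];
      nij += rij[c]*rij[c]; nkj += rkj[c]*rkj[c]; dot += rij[c]*rkj[c];
    }
    nij = std::sqrt(nij); nkj = std::sqrt(nkj);
    double ct = dot / (nij * nkj);
    ct = std::max(-1.0, std::min(1.0, ct));
    const double st = std::max(std::sqrt(1.0 - ct * ct), 1e-8);
    const double theta = std::acos(ct);
    const double p = angK[a] * (theta - angT0[a]) / st;
    for (int c = 0; c < 3; ++c) {
      // dtheta/dx_i = g_i / sin(theta); F = -k (theta - theta0) dtheta/dx
      const double gi = (ct * rij[c] / nij - rkj[c] / nkj) / nij;
      const double gk = (ct * rkj[c] / nkj - rij[c] / nij) / nkj;
      F[3*i+c] -= p * gi;
      F[3*k+c] -= p * gk;
      F[3*j+c] += p * (gi + gk);
    }
  }
  // optional external harmonic tether (test harness for thermostat checks)
  if (tetherK > 0) {
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        F[3*i+c] -= tetherK * (x[3*i+c] - tetherC[c]);
  }
  // receptor interactions: WCA repulsion always; screened Coulomb optionally
  const int m = rx.nrow();
  const double swOn = elecCutoff - 2.0, swOff = elecCutoff;
  const double denomSw = std::pow(swOff*swOff - swOn*swOn, 3);
  for (int i = 0; i < n; ++i) {
    for (int jr = 0; jr < m; ++jr) {
      double d[3], r2 = 0;
      for (int c = 0; c < 3; ++c) { d[c] = x[3*i+c] - rx(jr, c); r2 += d[c]*d[c]; }
      const double r = std::sqrt(r2);
      const double contact = lrad[i] + rrad[jr];
      if (r < contact && wcaEps > 0) {  // WCA: zero beyond 2^(1/6) sigma = contact
        const double sig = contact * 0.8908987181403393;  // contact * 2^(-1/6)
        const double sr6 = std::pow(sig / r, 6);
        const double fmag = 24.0 * wcaEps * (2.0 * sr6 * sr6 - sr6) / r2;
        for (int c = 0; c < 3; ++c) F[3*i+c] += fmag * d[c];
      }
      if (localElec && r < elecCutoff && lq[i] != 0.0 && rq[jr] != 0.0) {
        // native implicit-solvent MD electrostatics: direct Coulomb
        // (eps = 1) plus Still GB polarization, with Born radii held
        // fixed across the cycle (they are supplied per cycle)
        double s = 1.0, ds = 0.0;
        if (r > swOn) {
          const double A = swOff*swOff - r2, B = swOff*swOff + 2*r2 - 3*swOn*swOn;
          s = A * A * B / denomSw;
          ds = 12.0 * r * A * (swOn*swOn - r2) / denomSw;
        }
        const double qq = K_COULOMB * lq[i] * rq[jr];
        const double RiRj = lborn[i] * rborn[jr];
        const double ee = std::exp(-r2 / (4.0 * RiRj));
        const double f = std::sqrt(r2 + RiRj * ee);
        const double epsFac = 1.0 - 1.0 / epsSolvent;
        const double e = qq * (1.0 / r - epsFac / f);
        const double dfdr = r * (1.0 - ee / 4.0) / f;
        const double dedr = qq * (-1.0 / r2 + epsFac * dfdr / (f * f));
        const double fr = -(ds * e + s * dedr);  // -(dE_switched/dr)
        for (int c = 0; c < 3; ++c) F[3*i+c] += fr * d[c] / r;
      }
    }
  }
  double fmax = 0;
  for (int i = 0; i < n; ++i) {
    double f2 = F[3*i]*F[3*i] + F[3*i+1]*F[3*i+1] + F[3*i+2]*F[3*i+2];
    if (f2 > fmax) fmax = f2;
  }
  return std::sqrt(fmax);
}

}  // namespace

// [[Rcpp::export(name = ".localForces")]]
NumericMatrix localForcesR(NumericMatrix x, IntegerMatrix bonds,
                           NumericVector bondR0, NumericVector bondK,
                           IntegerMatrix angles, NumericVector angT0,
                           NumericVector angK, NumericMatrix rx,
                           NumericVector rq, NumericVector rrad,
                           NumericVector lq, NumericVector lrad,
                           NumericVector rborn, NumericVector lborn,
                           double wcaEps, bool localElec, double elecCutoff,
                           double epsSolvent,
                           double tetherK, NumericVector tetherC) {
  const int n = x.nrow();
  std::vector<double> xf(3 * n), Ff(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) xf[3*i+c] = x(i, c);
  localForcesImpl(xf.data(), n, bonds, bondR0, bondK, angles, angT0, angK,
                  rx, rq, rrad, lq, lrad, rborn, lborn, wcaEps, localElec,
                  elecCutoff, epsSolvent, tetherK, tetherC, Ff.data());
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = Ff[3*i+c];
  return out;
}

// One steering cycle of BAOAB Langevin dynamics with the steering force
// held constant across the cycle. Returns the final state, optional
// recorded positions, and diagnostics.
// [[Rcpp::export(name = ".langevinCycle")]]
List langevinCycle(NumericMatrix x0, NumericMatrix v0, NumericVector mass,
                   IntegerMatrix bonds, NumericVector bondR0, NumericVector bondK,
                   IntegerMatrix angles, NumericVector angT0, NumericVector angK,
                   NumericMatrix rx, NumericVector rq, NumericVector rrad,
                   NumericVector lq, NumericVector lrad,
                   NumericVector rborn, NumericVector lborn,
                   NumericMatrix steer, double dtFs, double gammaPs,
                   double temperature, int nsteps,
                   double wcaEps, bool localElec, double elecCutoff,
                   double epsSolvent,
                   double tetherK, NumericVector tetherC,
                   double seed1, double seed2,
                   int recordEvery, double blowupThreshold) {
  const int n = x0.nrow();
  const double kB = 0.0019872041;
  const double kT = kB * temperature;
  const double gammaFs = gammaPs * 1e-3;
  const double c1 = std::exp(-gammaFs * dtFs);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  Xoshiro rng(((uint64_t)(uint32_t)seed1 << 32) ^ (uint64_t)(uint32_t)seed2);

  std::vector<double> x(3 * n), v(3 * n), F(3 * n), sigma(n), accFac(n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) { x[3*i+c] = x0(i, c); v[3*i+c] = v0(i, c); }
    sigma[i] = (temperature > 0) ? std::sqrt(ACC_CONV * kT / mass[i]) : 0.0;
    accFac[i] = ACC_CONV / mass[i];
  }
  auto addSteer = [&](double *Fv) {
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) Fv[3*i+c] += steer(i, c);
  };
  double fmax = localForcesImpl(x.data(), n, bonds, bondR0, bondK, angles,
                                angT0, angK, rx, rq, rrad, lq, lrad, rborn,
                                lborn, wcaEps, localElec, elecCutoff,
                                epsSolvent, tetherK, tetherC, F.data());
  addSteer(F.data());

  int nrec = recordEvery > 0 ? nsteps / recordEvery : 0;
  NumericMatrix records(nrec, 3 * n);
  int irec = 0;
  bool blewUp = false;
  int blowStep = -1;
  double keAccum = 0.0;

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i) {
      const double half = 0.5 * dtFs * accFac[i];
      for (int c = 0; c < 3; ++c) {
        v[3*i+c] += half * F[3*i+c];
        x[3*i+c] += 0.5 * dtFs * v[3*i+c];
      }
      for (int c = 0; c < 3; ++c) {
        v[3*i+c] = c1 * v[3*i+c] + c2 * sigma[i] * rng.gauss();
        x[3*i+c] += 0.5 * dtFs * v[3*i+c];
      }
    }
    fmax = localForcesImpl(x.data(), n, bonds, bondR0, bondK, angles,
                           angT0, angK, rx, rq, rrad, lq, lrad, rborn,
                           lborn, wcaEps, localElec, elecCutoff,
                           epsSolvent, tetherK, tetherC, F.data());
    addSteer(F.data());
    if (fmax > blowupThreshold || !std::isfinite(fmax)) {
      blewUp = true; blowStep = step; break;
    }
    for (int i = 0; i < n; ++i) {
      const double half = 0.5 * dtFs * accFac[i];
      for (int c = 0; c < 3; ++c) v[3*i+c] += half * F[3*i+c];
    }
    double ke = 0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] +
                             v[3*i+2]*v[3*i+2]) / ACC_CONV;
    keAccum += ke;
    bool bad = false;
    for (int i = 0; i < 3 * n; ++i)
      if (!std::isfinite(x[i])) { bad = true; break; }
    if (bad) { blewUp = true; blowStep = step; break; }
    if (recordEvery > 0 && step % recordEvery == 0 && irec < nrec) {
      for (int i = 0; i < 3 * n; ++i) records(irec, i) = x[i];
      ++irec;
    }
  }
  NumericMatrix xo(n, 3), vo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) { xo(i, c) = x[3*i+c]; vo(i, c) = v[3*i+c]; }
  return List::create(_["x"] = xo, _["v"] = vo, _["blewUp"] = blewUp,
                      _["blowStep"] = blowStep,
                      _["keMean"] = keAccum / std::max(1, nsteps),
                      _["records"] = records);
}
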