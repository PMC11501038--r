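#include <Rcpp.h>
#include <cmath>

#ifdef __GNUC__
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif
using namespace Rcpp;

// Heun (predictor-corrector) integrator for the three-species
// floor-plate / Shh reaction-diffusion system on a uniformly growing
// 1-D domain, solved in mapped coordinates x-bar in [0,1].
//
// Parameter vector layout (hour units throughout):
//   0 c_S_to_F, 1 c_S_to_N, 2 kappa_F, 3 kappa_N, 4 K_N_to_F, 5 K_F_to_N,
//   6 kappa_F_to_S, 7 alpha_F, 8 alpha_N, 9 alpha_S, 10 gamma_F, 11 gamma_N,
//   12 gamma_S, 13 D_S (um^2/h), 14 m_N_to_F, 15 m_F_to_N
//
// growth mode: 0 none, 1 linear, 2 exponential
// source mode: 0 pulse, 1 flux, 2 flux_off

static inline double hillpow(double base, double m) {
  if (m == 3.0) return base * base * base;
  if (m == 2.0) return base * base;
  if (m == 1.0) return base;
  return std::pow(base, m);
}

struct Model {
  double cSF, cSN, kF, kN, KNF, KFN, kFS;
  double aF, aN, aS, gF, gN, gS, DS, mNF, mFN;
  int n;           // spatial bins
  double dx;       // bin width in mapped coordinates (1/n)
  int growth_mode; double L0, kp, tau, tend;
  int source_mode; double Sinit, jflux, toff;

  double length(double t) const {
    if (growth_mode == 1) return L0 + kp * t;
    if (growth_mode == 2) return L0 * std::exp(t / tau);
    return L0;
  }
  double length_dot(double t) const {
    if (growth_mode == 1) return kp;
    if (growth_mode == 2) return (L0 / tau) * std::exp(t / tau);
    return 0.0;
  }
  // boundary influx (amount per unit time, a.u. um / h) at time t;
  // the flux condition is imposed by a mirrored (centered-difference)
  // ghost bin, so the printed j_Shh (a.u./s) enters as 2 * 3600 * j
  double influx(double t) const {
    if (source_mode == 1) return 7200.0 * jflux;
    if (source_mode == 2 && t < toff) return 7200.0 * jflux;
    return 0.0;
  }

  void rhs(const std::vector<double>& F, const std::vector<double>& N,
           const std::vector<double>& S, double t,
           std::vector<double>& dF, std::vector<double>& dN,
           std::vector<double>& dS) const {
    const double L = length(t);
    const double dil = length_dot(t) / L;
    const double dc = DS / (L * L * dx * dx);
    const double jin = influx(t) / (L * dx);
    const double gFd = gF + dil, gNd = gN + dil, gSd = gS + dil;
    const double* RESTRICT f = F.data();
    const double* RESTRICT nn = N.data();
    const double* RESTRICT s = S.data();
    double* RESTRICT df = dF.data();
    double* RESTRICT dn = dN.data();
    double* RESTRICT ds = dS.data();
    const bool cubic = (mNF == 3.0 && mFN == 3.0);
    if (cubic) {
      for (int i = 0; i < n; ++i) {
        const double actF = kF * (1.0 + cSF * s[i]);
        const double bF = 1.0 + KNF * nn[i];
        const double repF = bF * bF * bF;
        df[i] = aF * actF / (repF + actF) - gFd * f[i];
        const double actN = kN * (1.0 + cSN * s[i]);
        const double bN = 1.0 + KFN * f[i];
        const double repN = bN * bN * bN;
        dn[i] = aN * actN / (repN + actN) - gNd * nn[i];
        const double h = kFS * f[i];
        ds[i] = aS * h / (1.0 + h) - gSd * s[i];
      }
    } else {
      for (int i = 0; i < n; ++i) {
        const double actF = kF * (1.0 + cSF * s[i]);
        const double repF = hillpow(1.0 + KNF * nn[i], mNF);
        df[i] = aF * actF / (repF + actF) - gFd * f[i];
        const double actN = kN * (1.0 + cSN * s[i]);
        const double repN = hillpow(1.0 + KFN * f[i], mFN);
        dn[i] = aN * actN / (repN + actN) - gNd * nn[i];
        const double h = kFS * f[i];
        ds[i] = aS * h / (1.0 + h) - gSd * s[i];
      }
    }
    // diffusion of S: 3-point stencil with reflective/flux closures
    ds[0] += dc * (s[1] - s[0]) + jin;
    for (int i = 1; i < n - 1; ++i)
      ds[i] += dc * (s[i - 1] - 2.0 * s[i] + s[i + 1]);
    ds[n - 1] += dc * (s[n - 2] - s[n - 1]);
  }
};

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector par,
              int growth_mode, double L0, double kp, double tau, double tend,
              int source_mode, double Sinit, double jflux, double toff,
              bool noise_on, double sigma_eta, double tau_eta,
              double noise_threshold,
              double dt, double record_every, int n_bins) {
  Model m;
  m.cSF = par[0]; m.cSN = par[1]; m.kF = par[2]; m.kN = par[3];
  m.KNF = par[4]; m.KFN = par[5]; m.kFS = par[6];
  m.aF = par[7]; m.aN = par[8]; m.aS = par[9];
  m.gF = par[10]; m.gN = par[11]; m.gS = par[12];
  m.DS = par[13]; m.mNF = par[14]; m.mFN = par[15];
  m.n = n_bins; m.dx = 1.0 / n_bins;
  m.growth_mode = growth_mode; m.L0 = L0; m.kp = kp; m.tau = tau; m.tend = tend;
  m.source_mode = source_mode; m.Sinit = Sinit; m.jflux = jflux; m.toff = toff;

  // dt <= 0 requests adaptive stepping at 40% of the diffusive
  // stability bound evaluated at the current (growing) length
  const bool adaptive = (dt <= 0.0);

  std::vector<double> F(n_bins, 0.0), N(n_bins, 10.0), S(n_bins, 0.0);
  if (source_mode == 0) S[0] = Sinit;

  std::vector<double> dF1(n_bins), dN1(n_bins), dS1(n_bins);
  std::vector<double> dF2(n_bins), dN2(n_bins), dS2(n_bins);
  std::vector<double> Fp(n_bins), Np(n_bins), Sp(n_bins);
  std::vector<double> etaF, etaN;
  double ou_h = -1.0, ou_decay = 0.0, ou_scale = 0.0;
  if (noise_on) {
    etaF.assign(n_bins, 0.0);
    etaN.assign(n_bins, 0.0);
  }

  // recording grid: 0, record_every, 2*record_every, ..., plus tend
  std::vector<double> rec_times;
  for (long i = 0; i * record_every < tend - 1e-9; ++i)
    rec_times.push_back(i * record_every);
  rec_times.push_back(tend);
  const int nrec = rec_times.size();

  NumericMatrix recF(n_bins, nrec), recN(n_bins, nrec), recS(n_bins, nrec);
  NumericVector recT(nrec), recL(nrec);
  double t_est = NA_REAL;

  int irec = 0;
  // snapshot at t = 0
  for (int i = 0; i < n_bins; ++i) {
    recF(i, 0) = F[i]; recN(i, 0) = N[i]; recS(i, 0) = S[i];
  }
  recT[0] = 0.0; recL[0] = m.length(0.0);
  if (F[0] > N[0]) t_est = 0.0;
  irec = 1;

  double t = 0.0;
  while (irec < nrec) {
    const double t_target = rec_times[irec];
    // advance to the next recording instant
    while (t < t_target - 1e-12) {
      double h = adaptive
        ? 0.4 * (m.dx * m.length(t)) * (m.dx * m.length(t)) / (2.0 * m.DS)
        : dt;
      bool at_target = false;
      if (t + h >= t_target - 1e-12) { h = t_target - t; at_target = true; }
      const double t1 = at_target ? t_target : t + h;
      m.rhs(F, N, S, t, dF1, dN1, dS1);
      for (int i = 0; i < n_bins; ++i) {
        Fp[i] = F[i] + h * dF1[i];
        Np[i] = N[i] + h * dN1[i];
        Sp[i] = S[i] + h * dS1[i];
      }
      m.rhs(Fp, Np, Sp, t1, dF2, dN2, dS2);
      for (int i = 0; i < n_bins; ++i) {
        F[i] += 0.5 * h * (dF1[i] + dF2[i]);
        N[i] += 0.5 * h * (dN1[i] + dN2[i]);
        S[i] += 0.5 * h * (dS1[i] + dS2[i]);
      }
      if (noise_on) {
        if (h != ou_h) {
          ou_h = h;
          ou_decay = std::exp(-h / tau_eta);
          ou_scale = sigma_eta *
            std::sqrt((1.0 - std::exp(-2.0 * h / tau_eta)) / tau_eta);
        }
        for (int i = 0; i < n_bins; ++i) {
          etaF[i] = etaF[i] * ou_decay + ou_scale * R::norm_rand();
          etaN[i] = etaN[i] * ou_decay + ou_scale * R::norm_rand();
          if (F[i] > noise_threshold) F[i] += etaF[i] * h;
          if (N[i] > noise_threshold) N[i] += etaN[i] * h;
        }
      }
      for (int i = 0; i < n_bins; ++i) {
        if (F[i] < 0.0) F[i] = 0.0;
        if (N[i] < 0.0) N[i] = 0.0;
        if (S[i] < 0.0) S[i] = 0.0;
      }
      t = t1;
    }
    // snapshot at rec_times[irec]
    for (int i = 0; i < n_bins; ++i) {
      recF(i, irec) = F[i]; recN(i, irec) = N[i]; recS(i, irec) = S[i];
    }
    recT[irec] = t_target;
    recL[irec] = m.length(t_target);
    if (!std::isfinite(F[0]) || !std::isfinite(N[0]) || !std::isfinite(S[0]) ||
        !std::isfinite(F[n_bins - 1]) || !std::isfinite(N[n_bins - 1]) ||
        !std::isfinite(S[n_bins - 1])) {
      stop("numerical failure (non-finite concentrations) at t = %.3f h",
           t_target);
    }
    if (ISNA(t_est) && F[0] > N[0]) t_est = t_target;
    ++irec;
  }
  double ssum = 0.0;
  for (int i = 0; i < n_bins; ++i) ssum += F[i] + N[i] + S[i];
  if (!std::isfinite(ssum))
    stop("numerical failure (non-finite concentrations) at t = %.3f h", tend);

  return List::create(_["time"] = recT, _["L"] = recL,
                      _["F"] = recF, _["N"] = recN, _["S"] = recS,
                      _["t_est"] = t_est,
                      _["dt"] = adaptive ? NA_REAL : dt);
}
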