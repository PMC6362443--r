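// Metropolis-within-Gibbs sampler for the joint dynamic N-occupancy /
// Cormack-Jolly-Seber model.
//
// Latent integer abundances (N1, S, G) are updated by +/-1 random-walk
// proposals respecting S_jt <= N_j,t-1; latent alive states Z by their
// Bernoulli full conditionals; regression coefficients and random effects by
// scalar adaptive random-walk Metropolis (proposal scales tuned during
// burn-in only, frozen afterwards); Kuo-Mallick indicators by their Gibbs
// full conditionals, with coefficients redrawn from the prior while switched
// out. Both data likelihoods share one survival (b) block.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int LN1 = 0, LS = 1, LG = 2, LOBSP = 3, LZ = 4, LOBSB = 5;

static inline double plg(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// log(1 - exp(q)) for q <= 0
static inline double log1m_exp(double q) {
  if (q >= 0) return R_NegInf;
  return (q > -0.6931471805599453) ? std::log(-std::expm1(q))
                                   : std::log1p(-std::exp(q));
}

struct Sampler {
  // dimensions
  int J, K, T, Rn, O, I, P;
  bool use_occ, use_band;
  // data
  std::vector<int> yP, obsv;            // length J*K*T; -1 = missing
  std::vector<double> dnbr, nboxv, sexv;
  NumericMatrix tfire, live, snag;      // J x T
  std::vector<int> tr, fv, bsite;       // 0-based
  IntegerMatrix yB;                     // I x T
  // priors
  std::vector<double> prmean, prsd;
  double sigma_upper;
  bool e0_logistic;
  // parameter indices
  int A0, A4, SIGA, B0, C0, D0, D1, D2, SIGD, E0, E1;
  // state
  std::vector<double> th, vmul;
  std::vector<int> v;                   // 15 indicators
  IntegerMatrix N, S, G, z;
  // caches (refreshed at each sweep start, used by latent updates)
  std::vector<double> lam, phi, gam, l1p, pBv;
  std::vector<double> llam, lphi, l1mphi, geta;  // log-scale caches
  std::vector<double> obs1tab;  // log P(y=1 | n) per (nbox,observer) combo
  int ncap;
  // detection-cell counts by (combo, N): the observation likelihood is
  // sum_combo [ l1p * sum(N over y=0 cells) + sum_n cnt1 * log(1-(1-p)^n) ]
  std::vector<double> sumN0;
  std::vector<int> cnt1;
  int cmax;
  double Lc[6];
  // proposal scales / acceptance bookkeeping
  std::vector<double> psd;
  std::vector<int> nprop, nacc, tprop, tacc;
  std::vector<int> ptype;               // 0 coef, 1 RE_a, 2 sig_a, 3 RE_d,
                                        // 4 sig_d, 5 e0
  std::vector<std::vector<int> > comps; // likelihood components per scalar
  // transect random-effect proposals only touch their own sites
  std::vector<std::vector<int> > sites_tr;
  // lgamma(n+1) table
  std::vector<double> lgt;

  double lgm(int n) {
    if (n >= 0 && n < (int)lgt.size()) return lgt[n];
    return R::lgammafn(n + 1.0);
  }
  double dpoisl(int n, double mu) {
    if (mu <= 0) return (n == 0) ? 0.0 : R_NegInf;
    return n * std::log(mu) - mu - lgm(n);
  }
  double dbinl(int s, int n, double p) {
    if (s < 0 || s > n) return R_NegInf;
    double out = lgm(n) - lgm(s) - lgm(n - s);
    if (s > 0) out += s * std::log(p);
    if (n - s > 0) out += (n - s) * std::log1p(-p);
    return out;
  }
  // cached-log variants used by the latent sweeps
  double dbinl2(int s, int n, double lp, double l1mp) {
    if (s < 0 || s > n) return R_NegInf;
    return lgm(n) - lgm(s) - lgm(n - s) + s * lp + (n - s) * l1mp;
  }
  double dpoisl2(int n, double eta, double mu) {
    return n * eta - mu - lgm(n);
  }

  // linear predictors (indicator multipliers applied)
  double loglam_j(int j) {
    return th[A0] + vmul[A0 + 1] * th[A0 + 1] * dnbr[j] +
           vmul[A0 + 2] * th[A0 + 2] * nboxv[j] +
           vmul[A0 + 3] * th[A0 + 3] * tfire(j, 0) +
           vmul[A4 + tr[j]] * th[A4 + tr[j]];
  }
  double logitphi(int j, int t) {  // transition into 0-based year t >= 1
    return th[B0] + vmul[B0 + 1] * th[B0 + 1] * nboxv[j] +
           vmul[B0 + 2] * th[B0 + 2] * tfire(j, t) +
           vmul[B0 + 3] * th[B0 + 3] * live(j, t) +
           vmul[B0 + 4] * th[B0 + 4] * snag(j, t);
  }
  double loggam_jt(int j, int t) {
    return th[C0] + vmul[C0 + 1] * th[C0 + 1] * nboxv[j] +
           vmul[C0 + 2] * th[C0 + 2] * tfire(j, t) +
           vmul[C0 + 3] * th[C0 + 3] * live(j, t) +
           vmul[C0 + 4] * th[C0 + 4] * snag(j, t);
  }
  double logitp(int nb, int o) {
    return th[D0] + vmul[D1] * th[D1] * nb + vmul[D2 + o] * th[D2 + o];
  }
  double logitpB(int i) { return th[E0] + vmul[E1] * th[E1] * sexv[i]; }

  // ---- component log-likelihoods, computed from current th/vmul ----
  double ll_N1() {
    if (!use_occ) return 0.0;
    double s = 0;
    for (int j = 0; j < J; j++) s += dpoisl(N(j, 0), std::exp(loglam_j(j)));
    return s;
  }
  double ll_S() {
    if (!use_occ || T < 2) return 0.0;
    double s = 0;
    for (int t = 1; t < T; t++)
      for (int j = 0; j < J; j++)
        s += dbinl(S(j, t), N(j, t - 1), plg(logitphi(j, t)));
    return s;
  }
  double ll_G() {
    if (!use_occ || T < 2) return 0.0;
    double s = 0;
    for (int t = 1; t < T; t++)
      for (int j = 0; j < J; j++)
        s += dpoisl(G(j, t), std::exp(loggam_jt(j, t)));
    return s;
  }
  double obsP_combo(int combo) {
    double l1pc = std::log1p(-plg(logitp(combo / O, combo % O)));
    double s = sumN0[combo] * l1pc;
    const int* c1 = &cnt1[combo * (cmax + 1)];
    for (int n = 0; n <= cmax; n++)
      if (c1[n]) s += c1[n] * log1m_exp(n * l1pc);
    return s;
  }
  double ll_obsP() {
    if (!use_occ) return 0.0;
    double s = 0;
    for (int combo = 0; combo < 2 * O; combo++) s += obsP_combo(combo);
    return s;
  }
  double ll_Z() {
    if (!use_band) return 0.0;
    double s = 0;
    for (int i = 0; i < I; i++) {
      int f = fv[i], js = bsite[i];
      for (int t = f + 1; t < T; t++) {
        double pr = z(i, t - 1) * plg(logitphi(js, t));
        s += z(i, t) ? std::log(pr) : std::log1p(-pr);
      }
    }
    return s;
  }
  double ll_obsB() {
    if (!use_band) return 0.0;
    double s = 0;
    for (int i = 0; i < I; i++) {
      double pbv = plg(logitpB(i));
      int f = fv[i];
      for (int t = f + 1; t < T; t++) {
        int y = yB(i, t);
        if (z(i, t) == 1)
          s += y ? std::log(pbv) : std::log1p(-pbv);
        else if (y == 1)
          return R_NegInf;
      }
    }
    return s;
  }
  double comp_ll(int c) {
    switch (c) {
      case LN1: return ll_N1();
      case LS: return ll_S();
      case LG: return ll_G();
      case LOBSP: return ll_obsP();
      case LZ: return ll_Z();
      default: return ll_obsB();
    }
  }

  void refresh() {
    for (int j = 0; j < J; j++) {
      double e = loglam_j(j);
      llam[j] = e; lam[j] = std::exp(e);
    }
    for (int t = 1; t < T; t++)
      for (int j = 0; j < J; j++) {
        int c = (t - 1) * J + j;
        double ph = plg(logitphi(j, t));
        phi[c] = ph; lphi[c] = std::log(ph); l1mphi[c] = std::log1p(-ph);
        double e = loggam_jt(j, t);
        geta[c] = e; gam[c] = std::exp(e);
      }
    for (int nb = 0; nb < 2; nb++)
      for (int o = 0; o < O; o++)
        l1p[nb * O + o] = std::log1p(-plg(logitp(nb, o)));
    for (int i = 0; i < I; i++) pBv[i] = plg(logitpB(i));
    // tabulated log P(y=1 | N = n) per combo, for the latent sweep
    if (use_occ) {
      int maxN = 1;
      for (int t = 0; t < T; t++)
        for (int j = 0; j < J; j++)
          if (N(j, t) > maxN) maxN = N(j, t);
      ncap = maxN + 8;
      obs1tab.assign(2 * O * (ncap + 1), R_NegInf);
      for (int combo = 0; combo < 2 * O; combo++)
        for (int n = 1; n <= ncap; n++)
          obs1tab[combo * (ncap + 1) + n] = log1m_exp(n * l1p[combo]);
    }
  }

  // detection-cell tallies; valid while N is fixed (parameter updates)
  void tabulate_obs() {
    if (!use_occ) return;
    cmax = ncap;
    sumN0.assign(2 * O, 0.0);
    cnt1.assign(2 * O * (cmax + 1), 0);
    for (int t = 0; t < T; t++)
      for (int k = 0; k < K; k++)
        for (int j = 0; j < J; j++) {
          int idx = j + J * (k + K * t);
          int y = yP[idx];
          if (y < 0) continue;
          int combo = ((int)nboxv[j]) * O + obsv[idx];
          int n = N(j, t);
          if (n > cmax) n = cmax;
          if (y == 0) sumN0[combo] += N(j, t);
          else cnt1[combo * (cmax + 1) + n]++;
        }
  }

  double obs_year(int j, int t, int n) {
    double s = 0;
    int nb = (int)nboxv[j];
    for (int k = 0; k < K; k++) {
      int idx = j + J * (k + K * t);
      int y = yP[idx];
      if (y < 0) continue;
      int combo = nb * O + obsv[idx];
      if (y == 0) s += n * l1p[combo];
      else s += (n <= ncap) ? obs1tab[combo * (ncap + 1) + n]
                            : log1m_exp(n * l1p[combo]);
    }
    return s;
  }

  // ---- latent updates ----
  void update_latent_occ() {
    for (int j = 0; j < J; j++) {
      int n = N(j, 0);
      int np = n + ((unif_rand() < 0.5) ? -1 : 1);
      if (np >= 0 && (T < 2 || S(j, 1) <= np)) {
        double dll = dpoisl2(np, llam[j], lam[j]) -
                     dpoisl2(n, llam[j], lam[j]) +
                     obs_year(j, 0, np) - obs_year(j, 0, n);
        if (T > 1)
          dll += dbinl2(S(j, 1), np, lphi[j], l1mphi[j]) -
                 dbinl2(S(j, 1), n, lphi[j], l1mphi[j]);
        if (std::log(unif_rand()) < dll) N(j, 0) = np;
      }
      for (int t = 1; t < T; t++) {
        int m = (int)(unif_rand() * 4.0);
        if (m > 3) m = 3;
        int dS = (m == 0) ? 1 : (m == 1) ? -1 : 0;
        int dG = (m == 2) ? 1 : (m == 3) ? -1 : 0;
        int Sp = S(j, t) + dS, Gp = G(j, t) + dG, Np = N(j, t) + dS + dG;
        if (Sp < 0 || Gp < 0 || Sp > N(j, t - 1)) continue;
        if (t + 1 < T && S(j, t + 1) > Np) continue;
        int c = (t - 1) * J + j;
        double dll = obs_year(j, t, Np) - obs_year(j, t, N(j, t));
        if (dS != 0)
          dll += dbinl2(Sp, N(j, t - 1), lphi[c], l1mphi[c]) -
                 dbinl2(S(j, t), N(j, t - 1), lphi[c], l1mphi[c]);
        if (dG != 0)
          dll += dpoisl2(Gp, geta[c], gam[c]) - dpoisl2(G(j, t), geta[c], gam[c]);
        if (t + 1 < T)
          dll += dbinl2(S(j, t + 1), Np, lphi[t * J + j], l1mphi[t * J + j]) -
                 dbinl2(S(j, t + 1), N(j, t), lphi[t * J + j],
                        l1mphi[t * J + j]);
        if (std::log(unif_rand()) < dll) {
          S(j, t) = Sp; G(j, t) = Gp; N(j, t) = Np;
        }
      }
    }
  }

  void update_latent_z() {
    for (int i = 0; i < I; i++) {
      int f = fv[i], js = bsite[i];
      double pbv = pBv[i];
      for (int t = f + 1; t < T; t++) {
        if (yB(i, t) == 1) { z(i, t) = 1; continue; }
        if (z(i, t - 1) == 0) { z(i, t) = 0; continue; }
        double ph = phi[(t - 1) * J + js];
        double w1 = ph * (1.0 - pbv), w0 = 1.0 - ph;
        if (t + 1 < T) {
          double ph2 = phi[t * J + js];
          if (z(i, t + 1) == 1) { w1 *= ph2; w0 = 0.0; }
          else w1 *= (1.0 - ph2);
        }
        z(i, t) = (unif_rand() < w1 / (w0 + w1)) ? 1 : 0;
      }
    }
  }

  // partial log-likelihood contributions of one transect / one observer
  double part_N1_tr(int r) {
    double s = 0;
    const std::vector<int>& js = sites_tr[r];
    for (size_t a = 0; a < js.size(); a++)
      s += dpoisl(N(js[a], 0), std::exp(loglam_j(js[a])));
    return s;
  }
  double part_obsP_o(int o) {
    return obsP_combo(o) + obsP_combo(O + o);
  }

  // ---- scalar Metropolis update ----
  void upd_scalar(int idx) {
    double cur = th[idx];
    double prop = cur + psd[idx] * norm_rand();
    nprop[idx]++; tprop[idx]++;
    int type = ptype[idx];
    if ((type == 2 || type == 4) && (prop <= 0 || prop >= sigma_upper)) return;
    if (type == 5 && !e0_logistic && (prop <= 0 || prop >= 1)) return;
    double lpr = 0;
    switch (type) {
      case 0:
        lpr = R::dnorm(prop, prmean[idx], prsd[idx], 1) -
              R::dnorm(cur, prmean[idx], prsd[idx], 1);
        break;
      case 1:
        lpr = R::dnorm(prop, 0.0, th[SIGA], 1) - R::dnorm(cur, 0.0, th[SIGA], 1);
        break;
      case 3:
        lpr = R::dnorm(prop, 0.0, th[SIGD], 1) - R::dnorm(cur, 0.0, th[SIGD], 1);
        break;
      case 2:
        for (int r = 0; r < Rn; r++)
          lpr += R::dnorm(th[A4 + r], 0.0, prop, 1) -
                 R::dnorm(th[A4 + r], 0.0, cur, 1);
        break;
      case 4:
        for (int o = 0; o < O; o++)
          lpr += R::dnorm(th[D2 + o], 0.0, prop, 1) -
                 R::dnorm(th[D2 + o], 0.0, cur, 1);
        break;
      case 5:
        if (e0_logistic)
          lpr = (prop - 2 * std::log1p(std::exp(prop))) -
                (cur - 2 * std::log1p(std::exp(cur)));
        break;
    }
    if (vmul[idx] == 0) {
      // indicator off: theta is refreshed from its prior by the indicator
      // Gibbs step, so skip (and do not let these moves drive adaptation)
      nprop[idx]--; tprop[idx]--;
      return;
    }
    if (use_occ && type == 1 && vmul[idx] != 0) {  // transect RE: own sites
      double lc = part_N1_tr(idx - A4);
      th[idx] = prop;
      double ln = part_N1_tr(idx - A4);
      if (std::log(unif_rand()) < ln - lc + lpr) {
        Lc[LN1] += ln - lc; nacc[idx]++; tacc[idx]++;
      } else th[idx] = cur;
      return;
    }
    if (use_occ && type == 3 && vmul[idx] != 0) {  // observer RE: own cells
      double lc = part_obsP_o(idx - D2);
      th[idx] = prop;
      double ln = part_obsP_o(idx - D2);
      if (std::log(unif_rand()) < ln - lc + lpr) {
        Lc[LOBSP] += ln - lc; nacc[idx]++; tacc[idx]++;
      } else th[idx] = cur;
      return;
    }
    double llcur = 0, llnew = 0, tmp[6];
    const std::vector<int>& cc = comps[idx];
    for (size_t a = 0; a < cc.size(); a++) llcur += Lc[cc[a]];
    th[idx] = prop;
    for (size_t a = 0; a < cc.size(); a++) {
      tmp[cc[a]] = comp_ll(cc[a]);
      llnew += tmp[cc[a]];
    }
    if (std::log(unif_rand()) < llnew - llcur + lpr) {
      for (size_t a = 0; a < cc.size(); a++) Lc[cc[a]] = tmp[cc[a]];
      nacc[idx]++; tacc[idx]++;
    } else {
      th[idx] = cur;
    }
  }

  // ---- indicator variable selection (Kuo-Mallick) ----
  // selectable order: a1 a2 a3 a4blk b1 b2 b3 b4 c1 c2 c3 c4 d1 d2blk e1
  void set_v(int si, double val) {
    if (si <= 2) vmul[A0 + 1 + si] = val;
    else if (si == 3) for (int r = 0; r < Rn; r++) vmul[A4 + r] = val;
    else if (si <= 7) vmul[B0 + (si - 3)] = val;
    else if (si <= 11) vmul[C0 + (si - 7)] = val;
    else if (si == 12) vmul[D1] = val;
    else if (si == 13) for (int o = 0; o < O; o++) vmul[D2 + o] = val;
    else vmul[E1] = val;
  }
  void sel_comps(int si, std::vector<int>& cc) {
    cc.clear();
    if (si <= 3) cc.push_back(LN1);
    else if (si <= 7) { cc.push_back(LS); cc.push_back(LZ); }
    else if (si <= 11) cc.push_back(LG);
    else if (si <= 13) cc.push_back(LOBSP);
    else cc.push_back(LOBSB);
  }
  void upd_indicators(const std::vector<int>& sel_active) {
    std::vector<int> cc;
    for (int si = 0; si < 15; si++) {
      if (!sel_active[si]) continue;
      sel_comps(si, cc);
      double l0[6], l1[6], ll0 = 0, ll1 = 0;
      set_v(si, 0);
      for (size_t a = 0; a < cc.size(); a++) { l0[cc[a]] = comp_ll(cc[a]); ll0 += l0[cc[a]]; }
      set_v(si, 1);
      for (size_t a = 0; a < cc.size(); a++) { l1[cc[a]] = comp_ll(cc[a]); ll1 += l1[cc[a]]; }
      double p1 = 1.0 / (1.0 + std::exp(ll0 - ll1));
      int nv = (unif_rand() < p1) ? 1 : 0;
      set_v(si, (double)nv);
      v[si] = nv;
      for (size_t a = 0; a < cc.size(); a++)
        Lc[cc[a]] = nv ? l1[cc[a]] : l0[cc[a]];
      if (nv == 0) {  // coefficient decoupled: full conditional is the prior
        if (si == 3)
          for (int r = 0; r < Rn; r++) th[A4 + r] = th[SIGA] * norm_rand();
        else if (si == 13)
          for (int o = 0; o < O; o++) th[D2 + o] = th[SIGD] * norm_rand();
        else {
          int idx = sel_theta(si);
          th[idx] = prmean[idx] + prsd[idx] * norm_rand();
        }
      }
    }
  }
  int sel_theta(int si) {
    if (si <= 2) return A0 + 1 + si;
    if (si <= 7) return B0 + (si - 3);
    if (si <= 11) return C0 + (si - 7);
    if (si == 12) return D1;
    return E1;
  }

  // ---- posterior-predictive squared-loss discrepancies ----
  void discrepancy(double* out) {
    double tobs = 0, trep = 0, tobsB = 0, trepB = 0;
    if (use_occ) {
      std::vector<double> tab(2 * O);
      for (int nb = 0; nb < 2; nb++)
        for (int o = 0; o < O; o++)
          tab[nb * O + o] = std::log1p(-plg(logitp(nb, o)));
      for (int t = 0; t < T; t++)
        for (int k = 0; k < K; k++)
          for (int j = 0; j < J; j++) {
            int idx = j + J * (k + K * t);
            int y = yP[idx];
            if (y < 0) continue;
            int n = N(j, t), nb = (int)nboxv[j];
            double pe = (n == 0) ? 0.0 : -std::expm1(n * tab[nb * O + obsv[idx]]);
            double yr = (unif_rand() < pe) ? 1.0 : 0.0;
            tobs += (y - pe) * (y - pe);
            trep += (yr - pe) * (yr - pe);
          }
    }
    if (use_band) {
      for (int i = 0; i < I; i++) {
        double pbv = plg(logitpB(i));
        int f = fv[i];
        for (int t = f + 1; t < T; t++) {
          double pe = z(i, t) ? pbv : 0.0;
          double yr = (unif_rand() < pe) ? 1.0 : 0.0;
          tobsB += (yB(i, t) - pe) * (yB(i, t) - pe);
          trepB += (yr - pe) * (yr - pe);
        }
      }
    }
    out[0] = tobs; out[1] = trep; out[2] = tobsB; out[3] = trepB;
  }
};

// [[Rcpp::export]]
List ob_mcmc_chain(List dat, List prior, List cfg, List init) {
  Sampler s;
  s.J = as<int>(dat["J"]); s.K = as<int>(dat["K"]); s.T = as<int>(dat["T"]);
  s.Rn = as<int>(dat["R"]); s.O = as<int>(dat["O"]); s.I = as<int>(dat["I"]);
  s.use_occ = as<bool>(dat["use_occ"]);
  s.use_band = as<bool>(dat["use_band"]);
  s.yP = as<std::vector<int> >(dat["yP"]);
  s.obsv = as<std::vector<int> >(dat["obs"]);
  s.dnbr = as<std::vector<double> >(dat["dnbr"]);
  s.nboxv = as<std::vector<double> >(dat["nbox"]);
  s.tfire = as<NumericMatrix>(dat["tfire"]);
  s.live = as<NumericMatrix>(dat["live"]);
  s.snag = as<NumericMatrix>(dat["snag"]);
  s.tr = as<std::vector<int> >(dat["transect"]);
  s.yB = as<IntegerMatrix>(dat["yB"]);
  s.fv = as<std::vector<int> >(dat["f"]);
  s.bsite = as<std::vector<int> >(dat["bsite"]);
  s.sexv = as<std::vector<double> >(dat["sex"]);

  s.prmean = as<std::vector<double> >(prior["mean"]);
  s.prsd = as<std::vector<double> >(prior["sd"]);
  s.sigma_upper = as<double>(prior["sigma_upper"]);
  s.e0_logistic = as<bool>(prior["e0_logistic"]);

  int J = s.J, T = s.T, Rn = s.Rn, O = s.O, I = s.I;
  s.A0 = 0; s.A4 = 4; s.SIGA = 4 + Rn;
  s.B0 = 5 + Rn; s.C0 = 10 + Rn; s.D0 = 15 + Rn; s.D1 = 16 + Rn;
  s.D2 = 17 + Rn; s.SIGD = 17 + Rn + O; s.E0 = 18 + Rn + O;
  s.E1 = 19 + Rn + O;
  s.P = 20 + Rn + O;

  s.th = as<std::vector<double> >(init["theta"]);
  if ((int)s.th.size() != s.P) stop("theta init has wrong length");
  s.v = as<std::vector<int> >(init["v"]);
  s.N = as<IntegerMatrix>(init["N"]);
  s.S = as<IntegerMatrix>(init["S"]);
  s.G = as<IntegerMatrix>(init["G"]);
  s.z = as<IntegerMatrix>(init["z"]);

  // indicator multipliers from initial v
  s.vmul.assign(s.P, 1.0);
  for (int si = 0; si < 15; si++) s.set_v(si, (double)s.v[si]);

  // parameter types and likelihood components per scalar
  s.ptype.assign(s.P, 0);
  for (int r = 0; r < Rn; r++) s.ptype[s.A4 + r] = 1;
  s.ptype[s.SIGA] = 2;
  for (int o = 0; o < O; o++) s.ptype[s.D2 + o] = 3;
  s.ptype[s.SIGD] = 4;
  s.ptype[s.E0] = 5;
  s.comps.assign(s.P, std::vector<int>());
  for (int idx = 0; idx < s.P; idx++) {
    if (idx <= 3 || (idx >= s.A4 && idx < s.SIGA)) s.comps[idx].push_back(LN1);
    else if (idx >= s.B0 && idx < s.C0) {
      s.comps[idx].push_back(LS); s.comps[idx].push_back(LZ);
    } else if (idx >= s.C0 && idx < s.D0) s.comps[idx].push_back(LG);
    else if (idx == s.D0 || idx == s.D1 ||
             (idx >= s.D2 && idx < s.SIGD)) s.comps[idx].push_back(LOBSP);
    else if (idx == s.E0 || idx == s.E1) s.comps[idx].push_back(LOBSB);
    // SIGA / SIGD: prior-only updates (empty component list)
  }

  int n_iter = as<int>(cfg["n_iter"]);
  int burn = as<int>(cfg["burn_in"]);
  int thin = as<int>(cfg["thin"]);
  bool adapt = as<bool>(cfg["adapt"]);
  bool select = as<bool>(cfg["select"]);
  std::vector<int> sel_active = as<std::vector<int> >(cfg["sel_active"]);
  std::vector<int> upd = as<std::vector<int> >(cfg["update"]);
  bool store_occ = s.use_occ, store_z = s.use_band;

  s.psd.assign(s.P, 0.1);
  s.psd[s.SIGA] = s.psd[s.SIGD] = 0.2;
  s.nprop.assign(s.P, 0); s.nacc.assign(s.P, 0);
  s.tprop.assign(s.P, 0); s.tacc.assign(s.P, 0);

  // partial-update index lists
  s.sites_tr.assign(Rn, std::vector<int>());
  for (int j = 0; j < J; j++) s.sites_tr[s.tr[j]].push_back(j);

  // lgamma(n+1) table
  int lgn = 2048;
  s.lgt.resize(lgn);
  for (int n = 0; n < lgn; n++) s.lgt[n] = R::lgammafn(n + 1.0);

  int JT1 = J * std::max(T - 1, 1);
  s.lam.assign(J, 0); s.llam.assign(J, 0);
  s.phi.assign(JT1, 0); s.lphi.assign(JT1, 0); s.l1mphi.assign(JT1, 0);
  s.gam.assign(JT1, 0); s.geta.assign(JT1, 0);
  s.l1p.assign(2 * O, 0); s.pBv.assign(std::max(I, 1), 0);
  s.ncap = 1; s.cmax = 1;

  s.refresh();
  s.tabulate_obs();
  for (int c = 0; c < 6; c++) s.Lc[c] = s.comp_ll(c);
  {
    double tot = 0;
    for (int c = 0; c < 6; c++) tot += s.Lc[c];
    if (!R_finite(tot))
      stop("non-finite initial log posterior: check initial latent states "
           "and parameter values");
  }

  int nkeep = (n_iter - burn) / thin;
  NumericMatrix out_th(nkeep, s.P), out_phi(nkeep, J * std::max(T - 1, 0));
  IntegerMatrix out_v(nkeep, 15);
  IntegerMatrix out_N(store_occ ? nkeep : 0, J * T);
  IntegerMatrix out_G(store_occ ? nkeep : 0, J * std::max(T - 1, 0));
  IntegerMatrix out_z(store_z ? nkeep : 0, I * T);
  NumericMatrix out_disc(nkeep, 4);
  NumericVector out_ll(nkeep);

  int kept = 0;
  for (int iter = 0; iter < n_iter; iter++) {
    s.refresh();
    if (s.use_occ) s.update_latent_occ();
    if (s.use_band && I > 0) s.update_latent_z();
    s.tabulate_obs();
    for (int c = 0; c < 6; c++) s.Lc[c] = s.comp_ll(c);
    for (int idx = 0; idx < s.P; idx++)
      if (upd[idx]) s.upd_scalar(idx);
    if (select) s.upd_indicators(sel_active);

    if (adapt && iter < burn && (iter + 1) % 50 == 0) {
      for (int idx = 0; idx < s.P; idx++) {
        if (s.nprop[idx] > 0) {
          double rate = (double)s.nacc[idx] / s.nprop[idx];
          s.psd[idx] *= std::exp(0.8 * (rate - 0.44));
          if (s.psd[idx] < 1e-4) s.psd[idx] = 1e-4;
          if (s.psd[idx] > 20) s.psd[idx] = 20;
        }
        s.nprop[idx] = 0; s.nacc[idx] = 0;
      }
      if (iter + 1 == burn) { /* frozen hereafter */ }
    }

    if (iter >= burn && (iter - burn) % thin == 0 && kept < nkeep) {
      for (int idx = 0; idx < s.P; idx++) out_th(kept, idx) = s.th[idx];
      for (int si = 0; si < 15; si++) out_v(kept, si) = s.v[si];
      for (int t = 1; t < T; t++)
        for (int j = 0; j < J; j++)
          out_phi(kept, (t - 1) * J + j) = plg(s.logitphi(j, t));
      if (store_occ) {
        for (int t = 0; t < T; t++)
          for (int j = 0; j < J; j++) out_N(kept, t * J + j) = s.N(j, t);
        for (int t = 1; t < T; t++)
          for (int j = 0; j < J; j++)
            out_G(kept, (t - 1) * J + j) = s.G(j, t);
      }
      if (store_z)
        for (int t = 0; t < T; t++)
          for (int i = 0; i < I; i++) out_z(kept, t * I + i) = s.z(i, t);
      double d[4];
      s.discrepancy(d);
      for (int a = 0; a < 4; a++) out_disc(kept, a) = d[a];
      double tot = 0;
      for (int c = 0; c < 6; c++) tot += s.Lc[c];
      out_ll[kept] = tot;
      kept++;
    }
  }

  NumericVector acc(s.P);
  for (int idx = 0; idx < s.P; idx++)
    acc[idx] = s.tprop[idx] > 0 ? (double)s.tacc[idx] / s.tprop[idx] : NA_REAL;

  return List::create(_["theta"] = out_th, _["v"] = out_v, _["phi"] = out_phi,
                      _["N"] = out_N, _["G"] = out_G, _["z"] = out_z,
                      _["disc"] = out_disc, _["loglik"] = out_ll,
                      _["accept"] = acc);
}
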