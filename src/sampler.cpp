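#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// log(1 + exp(x)), overflow-safe
static inline double log1p_exp(double x) {
  if (x > 35.0) return x;
  if (x > 18.0) return x + std::exp(-x);
  if (x > -37.0) return std::log1p(std::exp(x));
  return std::exp(x);
}

static inline double powpos(double x, double r) {
  return x > 0.0 ? std::pow(x, r) : 0.0;
}

// Bernoulli log-likelihood of one trial under the softmax choice rule.
// s = mu * (u(gamble) - u(guaranteed)); clipped below at clip_lp so a single
// saturated trial can never drive the posterior density to -Inf.
static inline double trial_ll(int y, double s, double clip_lp) {
  double lt = y ? -log1p_exp(-s) : -log1p_exp(s);
  return lt < clip_lp ? clip_lp : lt;
}

// Total choice log-likelihood given per-session value parameters on the
// natural scale. Sessions are contiguous blocks of the (sorted) trial arrays;
// sess_start is 0-based with length J+1.
// [[Rcpp::export(name = ".cpp_total_loglik")]]
double cpp_total_loglik(NumericVector gain, NumericVector lossmag,
                        NumericVector guar, IntegerVector y,
                        IntegerVector sess_start,
                        NumericVector rho, NumericVector lam, NumericVector mu,
                        double clip_lp) {
  int J = rho.size();
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    for (int t = sess_start[j]; t < sess_start[j + 1]; ++t) {
      double du = 0.5 * powpos(gain[t], rho[j]) -
                  0.5 * lam[j] * powpos(lossmag[t], rho[j]) -
                  powpos(guar[t], rho[j]);
      ll += trial_ll(y[t], mu[j] * du, clip_lp);
    }
  }
  return ll;
}

// ---------------------------------------------------------------------------
// One MCMC chain for the hierarchical prospect-theory model.
//
// Parameterization (non-centered): for each value parameter k in
// {rho, lambda, mu} and subject i,
//   log theta_{i,j}[k] = thetaM[k] + thetaV[k] * z0[i,k]
//                      + mod_j * (dSM[k] + dSV[k] * zS[i,k])
//                      + day_j * (dDM[k] + dDV[k] * zD[i,k])
// with z* ~ N(0,1). mod_j is the stress indicator (condition model) or the
// session Delta-cortisol value (covariate model).
//
// Sampler: adaptive scalar Metropolis-within-Gibbs (Robbins-Monro adaptation
// of log proposal scales toward 0.44 acceptance during warmup only). Powers
// gain^rho etc. are cached per trial and recomputed only when a proposal
// touches rho.
// ---------------------------------------------------------------------------

struct ChainData {
  NumericVector gain, lossmag, guar;
  IntegerVector y;
  IntegerVector sess_start; // J+1, 0-based
  IntegerVector ssub;       // J, 0-based subject index
  NumericVector sday, smod; // J
  int S, J, N;
  double clip_lp;
};

class PTChain {
public:
  ChainData d;
  // hyperparameters: 0-2 thetaM, 3-5 thetaV, 6-8 dSM, 9-11 dSV,
  //                  12-14 dDM, 15-17 dDV
  std::vector<double> hyper;
  std::vector<double> z0, zS, zD; // S x 3, column-major (i + S*k)
  std::vector<double> par;        // J x 3 natural-scale (rho,lam,mu), j + J*k
  std::vector<double> sll;        // per-session loglik
  std::vector<double> powg, powl, pows; // per-trial powers at current rho
  std::vector<double> tpg, tpl, tps;    // proposal buffers
  std::vector<std::vector<int> > sub_sess; // sessions per subject
  // adaptation state: one log-scale per scalar
  std::vector<double> lsc;
  std::vector<long> cnt;
  std::vector<double> prior_sd; // [0] thetaM sd, [1] effect-mean sd, [2] SD half-normal scale
  bool adapting;

  PTChain(const ChainData& dat, NumericVector init_hyper, NumericVector psd)
      : d(dat) {
    hyper.assign(init_hyper.begin(), init_hyper.end());
    z0.assign(d.S * 3, 0.0);
    zS.assign(d.S * 3, 0.0);
    zD.assign(d.S * 3, 0.0);
    par.assign(d.J * 3, 0.0);
    sll.assign(d.J, 0.0);
    powg.assign(d.N, 0.0);
    powl.assign(d.N, 0.0);
    pows.assign(d.N, 0.0);
    tpg.assign(d.N, 0.0);
    tpl.assign(d.N, 0.0);
    tps.assign(d.N, 0.0);
    sub_sess.assign(d.S, std::vector<int>());
    for (int j = 0; j < d.J; ++j) sub_sess[d.ssub[j]].push_back(j);
    int nsc = 18 + 9 * d.S;
    lsc.assign(nsc, std::log(0.1));
    for (int i = 18; i < nsc; ++i) lsc[i] = std::log(0.5);
    cnt.assign(nsc, 0);
    prior_sd.assign(psd.begin(), psd.end());
    adapting = true;
    init_joint();
    for (int j = 0; j < d.J; ++j)
      for (int k = 0; k < 3; ++k) par[j + d.J * k] = session_par(j, k);
    for (int j = 0; j < d.J; ++j) {
      sll[j] = eval_session(j, par[j], par[j + d.J], par[j + 2 * d.J], true);
      commit_pows(j);
    }
  }

  double session_par(int j, int k) const {
    int i = d.ssub[j];
    double lp = hyper[k] + hyper[3 + k] * z0[i + d.S * k] +
                d.smod[j] * (hyper[6 + k] + hyper[9 + k] * zS[i + d.S * k]) +
                d.sday[j] * (hyper[12 + k] + hyper[15 + k] * zD[i + d.S * k]);
    return std::exp(lp);
  }

  // loglik of session j at given params; if new_rho, powers are written to
  // the proposal buffers (call commit_pows on acceptance)
  double eval_session(int j, double rho, double lam, double mu, bool new_rho) {
    double ll = 0.0;
    int t0 = d.sess_start[j], t1 = d.sess_start[j + 1];
    if (new_rho) {
      for (int t = t0; t < t1; ++t) {
        tpg[t] = powpos(d.gain[t], rho);
        tpl[t] = powpos(d.lossmag[t], rho);
        tps[t] = powpos(d.guar[t], rho);
        double du = 0.5 * tpg[t] - 0.5 * lam * tpl[t] - tps[t];
        ll += trial_ll(d.y[t], mu * du, d.clip_lp);
      }
    } else {
      for (int t = t0; t < t1; ++t) {
        double du = 0.5 * powg[t] - 0.5 * lam * powl[t] - pows[t];
        ll += trial_ll(d.y[t], mu * du, d.clip_lp);
      }
    }
    return ll;
  }

  void commit_pows(int j) {
    for (int t = d.sess_start[j]; t < d.sess_start[j + 1]; ++t) {
      powg[t] = tpg[t];
      powl[t] = tpl[t];
      pows[t] = tps[t];
    }
  }

  void adapt(int idx, bool acc) {
    cnt[idx]++;
    if (!adapting) return;
    double g = 2.0 / std::sqrt((double)cnt[idx]);
    if (g > 0.25) g = 0.25;
    lsc[idx] += g * ((acc ? 1.0 : 0.0) - 0.44);
  }

  // generic scalar MH step for a subject-level z (block 0/1/2 = base/S/D)
  void update_z(int block, int i, int k) {
    std::vector<double>& z = block == 0 ? z0 : (block == 1 ? zS : zD);
    int idx = 18 + (block * 3 + k) * d.S + i;
    double zc = z[i + d.S * k];
    double zp = zc + std::exp(lsc[idx]) * norm_rand();
    double la = 0.5 * (zc * zc - zp * zp); // N(0,1) prior
    // affected sessions
    std::vector<int> js;
    std::vector<double> newll, newpar;
    for (size_t a = 0; a < sub_sess[i].size(); ++a) {
      int j = sub_sess[i][a];
      double w = block == 0 ? 1.0 : (block == 1 ? d.smod[j] : d.sday[j]);
      if (w == 0.0) continue;
      js.push_back(j);
    }
    if (js.empty()) { // prior-only: always defined, cheap MH
      if (la >= 0.0 || unif_rand() < std::exp(la)) {
        z[i + d.S * k] = zp;
        adapt(idx, true);
      } else adapt(idx, false);
      return;
    }
    z[i + d.S * k] = zp; // tentatively
    for (size_t a = 0; a < js.size(); ++a) {
      int j = js[a];
      double np = session_par(j, k);
      double rho = k == 0 ? np : par[j];
      double lam = k == 1 ? np : par[j + d.J];
      double mu = k == 2 ? np : par[j + 2 * d.J];
      double ll = eval_session(j, rho, lam, mu, k == 0);
      newll.push_back(ll);
      newpar.push_back(np);
      la += ll - sll[j];
    }
    if (la >= 0.0 || unif_rand() < std::exp(la)) {
      for (size_t a = 0; a < js.size(); ++a) {
        int j = js[a];
        par[j + d.J * k] = newpar[a];
        sll[j] = newll[a];
        if (k == 0) commit_pows(j);
      }
      adapt(idx, true);
    } else {
      z[i + d.S * k] = zc;
      adapt(idx, false);
    }
  }

  void update_hyper(int h) {
    int k = h % 3;
    bool is_sd = (h >= 3 && h < 6) || (h >= 9 && h < 12) || (h >= 15);
    double xc = hyper[h];
    double xp = xc + std::exp(lsc[h]) * norm_rand();
    if (is_sd && xp <= 0.0) { adapt(h, false); return; }
    double psd = h < 3 ? prior_sd[0] : (is_sd ? prior_sd[2] : prior_sd[1]);
    double la = (xc * xc - xp * xp) / (2.0 * psd * psd);
    hyper[h] = xp; // tentatively
    std::vector<int> js;
    std::vector<double> newll, newpar;
    for (int j = 0; j < d.J; ++j) {
      double w = h < 6 ? 1.0 : (h < 12 ? d.smod[j] : d.sday[j]);
      if (w == 0.0) continue;
      js.push_back(j);
    }
    for (size_t a = 0; a < js.size(); ++a) {
      int j = js[a];
      double np = session_par(j, k);
      double rho = k == 0 ? np : par[j];
      double lam = k == 1 ? np : par[j + d.J];
      double mu = k == 2 ? np : par[j + 2 * d.J];
      double ll = eval_session(j, rho, lam, mu, k == 0);
      newll.push_back(ll);
      newpar.push_back(np);
      la += ll - sll[j];
    }
    if (la >= 0.0 || unif_rand() < std::exp(la)) {
      for (size_t a = 0; a < js.size(); ++a) {
        int j = js[a];
        par[j + d.J * k] = newpar[a];
        sll[j] = newll[a];
        if (k == 0) commit_pows(j);
      }
      adapt(h, true);
    } else {
      hyper[h] = xc;
      adapt(h, false);
    }
  }

  // ---- adaptive joint updates for the mean hyperparameters ----
  // The posterior correlates the population means strongly (rho trades off
  // against lambda along the indifference line, against mu through the
  // utility scale, and baselines against effect means through the group
  // structure), so scalar updates alone mix slowly. Haario-style
  // multivariate proposals with covariance learned during warmup fix this:
  // one 3-d block per mean vector plus one 9-d block over all means.
  static const int NJB = 4;
  std::vector<std::vector<int> > jidx; // hyper indices per block
  std::vector<std::vector<double> > jmean, jcov, jchol;
  std::vector<double> jls;
  std::vector<long> jn;
  std::vector<bool> jready;

  void init_joint() {
    int m3[3] = {0, 1, 2}, s3[3] = {6, 7, 8}, d3[3] = {12, 13, 14};
    jidx.assign(NJB, std::vector<int>());
    jidx[0].assign(m3, m3 + 3);
    jidx[1].assign(s3, s3 + 3);
    jidx[2].assign(d3, d3 + 3);
    for (int k = 0; k < 3; ++k) {
      jidx[3].push_back(m3[k]);
      jidx[3].push_back(s3[k]);
      jidx[3].push_back(d3[k]);
    }
    jmean.assign(NJB, std::vector<double>());
    jcov.assign(NJB, std::vector<double>());
    jchol.assign(NJB, std::vector<double>());
    for (int b = 0; b < NJB; ++b) {
      int p = jidx[b].size();
      jmean[b].assign(p, 0.0);
      jcov[b].assign(p * p, 0.0);
      jchol[b].assign(p * p, 0.0);
    }
    jls.assign(NJB, std::log(0.3));
    jn.assign(NJB, 0);
    jready.assign(NJB, false);
  }

  void joint_accumulate(int b) {
    int p = jidx[b].size();
    jn[b]++;
    double w = 1.0 / jn[b];
    std::vector<double> dm(p);
    for (int k = 0; k < p; ++k) {
      double x = hyper[jidx[b][k]];
      dm[k] = x - jmean[b][k];
      jmean[b][k] += w * dm[k];
    }
    for (int r = 0; r < p; ++r)
      for (int c = 0; c < p; ++c)
        jcov[b][p * r + c] += w * (dm[r] * (hyper[jidx[b][c]] - jmean[b][c]) -
                                   jcov[b][p * r + c]);
  }

  bool joint_chol(int b) {
    int p = jidx[b].size();
    if (jn[b] < 100) return false;
    std::vector<double> a(jcov[b]);
    for (int r = 0; r < p; ++r) a[p * r + r] += 1e-10 + 1e-6 * a[p * r + r];
    std::vector<double> L(p * p, 0.0);
    for (int r = 0; r < p; ++r) {
      for (int c = 0; c <= r; ++c) {
        double s = a[p * r + c];
        for (int k = 0; k < c; ++k) s -= L[p * r + k] * L[p * c + k];
        if (r == c) {
          if (s <= 0.0) return false;
          L[p * r + c] = std::sqrt(s);
        } else L[p * r + c] = s / L[p * c + c];
      }
    }
    jchol[b] = L;
    return true;
  }

  // does hyper index h scale with a session weight?
  double hyper_weight(int h, int j) const {
    if (h < 6) return 1.0;
    if (h < 12) return d.smod[j];
    return d.sday[j];
  }

  void update_joint(int b) {
    if (adapting) {
      joint_accumulate(b);
      if (jn[b] % 50 == 0) jready[b] = joint_chol(b);
    }
    if (!jready[b]) return;
    int p = jidx[b].size();
    double scale = std::exp(jls[b]) * 2.38 / std::sqrt((double)p);
    std::vector<double> eta(p), xc(p), xp(p);
    for (int k = 0; k < p; ++k) eta[k] = norm_rand();
    double la = 0.0;
    for (int k = 0; k < p; ++k) {
      int h = jidx[b][k];
      xc[k] = hyper[h];
      double step = 0.0;
      for (int c = 0; c <= k; ++c) step += jchol[b][p * k + c] * eta[c];
      xp[k] = xc[k] + scale * step;
      double psd = h < 3 ? prior_sd[0] : prior_sd[1];
      la += (xc[k] * xc[k] - xp[k] * xp[k]) / (2.0 * psd * psd);
    }
    for (int k = 0; k < p; ++k) hyper[jidx[b][k]] = xp[k];
    std::vector<int> js;
    for (int j = 0; j < d.J; ++j) {
      bool touched = false;
      for (int k = 0; k < p && !touched; ++k)
        if (hyper_weight(jidx[b][k], j) != 0.0) touched = true;
      if (touched) js.push_back(j);
    }
    std::vector<double> newll(js.size()), newpar(3 * js.size());
    for (size_t a2 = 0; a2 < js.size(); ++a2) {
      int j = js[a2];
      double rho = session_par(j, 0), lam = session_par(j, 1),
             mu = session_par(j, 2);
      newll[a2] = eval_session(j, rho, lam, mu, true);
      newpar[3 * a2] = rho;
      newpar[3 * a2 + 1] = lam;
      newpar[3 * a2 + 2] = mu;
      la += newll[a2] - sll[j];
    }
    bool acc = la >= 0.0 || unif_rand() < std::exp(la);
    if (acc) {
      for (size_t a2 = 0; a2 < js.size(); ++a2) {
        int j = js[a2];
        par[j] = newpar[3 * a2];
        par[j + d.J] = newpar[3 * a2 + 1];
        par[j + 2 * d.J] = newpar[3 * a2 + 2];
        sll[j] = newll[a2];
        commit_pows(j);
      }
    } else {
      for (int k = 0; k < p; ++k) hyper[jidx[b][k]] = xc[k];
    }
    if (adapting) {
      double g = 2.0 / std::sqrt((double)(jn[b] + 1));
      if (g > 0.25) g = 0.25;
      jls[b] += g * ((acc ? 1.0 : 0.0) - 0.23);
    }
  }

  // ---- interweaving (ASIS) update of the group mean/SD pairs ----
  // Re-express subject deviates in centered form c_i = M + V z_i (which is
  // exactly what enters the likelihood), Gibbs-update M and MH-update V
  // under the Gaussian population density and the priors while holding the
  // c_i fixed, then map back. The likelihood is invariant, so this costs no
  // likelihood evaluations, and it decorrelates the SD hyperparameters from
  // the deviates — the non-centered sampler alone mixes those poorly when
  // subjects are strongly data-informed.
  void interweave(int b) {
    int offM = b == 0 ? 0 : (b == 1 ? 6 : 12);
    int offV = offM + 3;
    std::vector<double>& z = b == 0 ? z0 : (b == 1 ? zS : zD);
    double psd = b == 0 ? prior_sd[0] : prior_sd[1];
    double sc = prior_sd[2];
    for (int k = 0; k < 3; ++k) {
      double M = hyper[offM + k], V = hyper[offV + k];
      std::vector<double> cv(d.S);
      for (int i = 0; i < d.S; ++i) cv[i] = M + V * z[i + d.S * k];
      // M | V, c : conjugate normal
      double prec = d.S / (V * V) + 1.0 / (psd * psd);
      double num = 0.0;
      for (int i = 0; i < d.S; ++i) num += cv[i];
      M = (num / (V * V)) / prec + norm_rand() / std::sqrt(prec);
      // V | M, c : MH on log V (half-normal prior, Jacobian included)
      double ssq = 0.0;
      for (int i = 0; i < d.S; ++i) {
        double dd = cv[i] - M;
        ssq += dd * dd;
      }
      double w = std::log(V);
      double lp_w = -(d.S - 1.0) * w - ssq / (2.0 * std::exp(2.0 * w)) -
                    std::exp(2.0 * w) / (2.0 * sc * sc);
      for (int rep = 0; rep < 3; ++rep) {
        double wp = w + 0.4 * norm_rand();
        double lp_p = -(d.S - 1.0) * wp - ssq / (2.0 * std::exp(2.0 * wp)) -
                      std::exp(2.0 * wp) / (2.0 * sc * sc);
        if (lp_p - lp_w > std::log(unif_rand())) {
          w = wp;
          lp_w = lp_p;
        }
      }
      V = std::exp(w);
      if (V < 1e-8) V = 1e-8;
      hyper[offM + k] = M;
      hyper[offV + k] = V;
      for (int i = 0; i < d.S; ++i) z[i + d.S * k] = (cv[i] - M) / V;
    }
  }

  void sweep() {
    for (int i = 0; i < d.S; ++i)
      for (int k = 0; k < 3; ++k) {
        update_z(0, i, k);
        update_z(1, i, k);
        update_z(2, i, k);
      }
    for (int h = 0; h < 18; ++h) update_hyper(h);
    // several joint-proposal rounds per sweep: they are cheap relative to
    // the scalar sweep and carry the mixing along the mean-ridge directions
    for (int rep = 0; rep < 2; ++rep)
      for (int b = 0; b < NJB; ++b) update_joint(b);
    for (int rep = 0; rep < 2; ++rep) update_joint(3);
    for (int b = 0; b < 3; ++b) interweave(b);
  }

  double total_ll() const {
    double s = 0.0;
    for (int j = 0; j < d.J; ++j) s += sll[j];
    return s;
  }
};

// [[Rcpp::export(name = ".cpp_run_chain")]]
List cpp_run_chain(NumericVector gain, NumericVector lossmag,
                   NumericVector guar, IntegerVector y,
                   IntegerVector sess_start, IntegerVector ssub,
                   NumericVector sday, NumericVector smod, int S,
                   int warmup, int keep, int thin,
                   NumericVector init_hyper, NumericVector prior_sd,
                   double clip_lp) {
  ChainData dat;
  dat.gain = gain; dat.lossmag = lossmag; dat.guar = guar; dat.y = y;
  dat.sess_start = sess_start; dat.ssub = ssub; dat.sday = sday;
  dat.smod = smod; dat.S = S; dat.J = ssub.size(); dat.N = gain.size();
  dat.clip_lp = clip_lp;
  PTChain ch(dat, init_hyper, prior_sd);

  int P = 18 + 9 * S;
  NumericMatrix out(keep, P);
  NumericVector out_ll(keep);

  for (int it = 0; it < warmup; ++it) {
    ch.sweep();
    if (it % 128 == 0) Rcpp::checkUserInterrupt();
  }
  ch.adapting = false;
  for (int r = 0; r < keep; ++r) {
    for (int s = 0; s < thin; ++s) ch.sweep();
    int c = 0;
    for (int h = 0; h < 18; ++h) out(r, c++) = ch.hyper[h];
    for (int k = 0; k < 3; ++k)
      for (int i = 0; i < S; ++i) out(r, c++) = ch.z0[i + S * k];
    for (int k = 0; k < 3; ++k)
      for (int i = 0; i < S; ++i) out(r, c++) = ch.zS[i + S * k];
    for (int k = 0; k < 3; ++k)
      for (int i = 0; i < S; ++i) out(r, c++) = ch.zD[i + S * k];
    out_ll[r] = ch.total_ll();
    if (r % 128 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws"] = out, _["loglik"] = out_ll);
}
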