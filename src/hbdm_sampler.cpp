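// Adaptive Metropolis-within-Gibbs sampler for the hierarchical Bayesian
// dynamic model of MAL change, plus posterior-trajectory helpers.
//
// The level-1 dynamics are deterministic (no process noise), so the joint
// model is a nonlinear hierarchical regression: each subject's trajectory
// is recomputed on the fly from (alpha, beta, gamma, x0).  Mixing across
// the hierarchy's soft ridges (retention vs self-training trade-off,
// truncated-normal location/scale ridges, sigmoid-saturated subjects) is
// handled by a cycle of moves:
//   * univariate adaptive random-walk updates of every parameter,
//   * per-subject 4-d adaptive-covariance block proposals,
//   * per-subject independence proposals from the conditional prior
//     (these traverse flat-likelihood directions in one jump),
//   * exact Gibbs for theta_alpha given the logit retention rates,
//   * ancillarity-style group moves: shift/scale one family's
//     (theta, sigma) with the subject draws transformed holding their
//     standardised residuals fixed (Jacobian-corrected),
//   * a global 8-d move on all hierarchy hypers with learned covariance
//     and the same z-fixed transform, which follows the joint ridge.
// All proposal scales and covariances adapt during warmup only; the
// kept-phase kernel is fixed.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmo(double x) { return 10.0 / (1.0 + std::exp(-0.2 * x)) - 5.0; }
static inline double ldnorm(double x, double mu, double s) {
  double z = (x - mu) / s;
  return -0.918938533204672741780329736406 - std::log(s) - 0.5 * z * z;
}
// normal truncated to [0, inf)
static inline double tn_lpdf(double v, double mu, double sigma) {
  if (v < 0) return R_NegInf;
  return ldnorm(v, mu, sigma) - R::pnorm(mu / sigma, 0.0, 1.0, 1, 1);
}
// inverse-gamma in shape/scale form
static inline double invgamma_lpdf(double s, double a, double b) {
  return a * std::log(b) - R::lgammafn(a) - (a + 1.0) * std::log(s) - b / s;
}
static inline double rtnorm0(double mu, double s) {
  for (int k = 0; k < 1000; ++k) { double v = R::rnorm(mu, s); if (v >= 0) return v; }
  return std::fabs(R::rnorm(mu, s));
}

// ---------------------------------------------------------------------------
// adaptive scale / covariance helpers

struct Adapt {
  std::vector<double> ls; std::vector<int> acc, try_;
  void init(int n, double s0) { ls.assign(n, std::log(s0)); acc.assign(n, 0); try_.assign(n, 0); }
  void tick(int j, bool a) { try_[j]++; if (a) acc[j]++; }
  void adapt_now(double target) {
    for (size_t j = 0; j < ls.size(); ++j) if (try_[j] >= 25) {
      ls[j] += ((double)acc[j] / try_[j] > target ? 0.1 : -0.1);
      acc[j] = 0; try_[j] = 0;
    }
  }
};

struct BlockAM {
  int d, n;
  std::vector<double> mean, cov, chol;
  double sc;
  void init(int dim) {
    d = dim; n = 0; mean.assign(d, 0.0); cov.assign(d*d, 0.0);
    chol.assign(d*d, 0.0); sc = 2.38 / std::sqrt((double)d);
    for (int i = 0; i < d; ++i) chol[i*d+i] = 0.05;
  }
  void push(const double *x) {
    n++;
    double w = 1.0 / n;
    for (int i = 0; i < d; ++i) {
      double dx = x[i] - mean[i];
      mean[i] += w * dx;
      for (int j = 0; j <= i; ++j) cov[i*d+j] += dx * (x[j] - mean[j]);
    }
  }
  void refresh() {
    if (n < 20 * d) return;
    std::vector<double> a(d*d, 0.0);
    for (int i = 0; i < d; ++i) for (int j = 0; j <= i; ++j) {
      double c = cov[i*d+j] / (n - 1);
      a[i*d+j] = c; a[j*d+i] = c;
    }
    for (int i = 0; i < d; ++i) a[i*d+i] += 1e-8 + 1e-6 * a[i*d+i];
    std::vector<double> L(d*d, 0.0);
    for (int i = 0; i < d; ++i) for (int j = 0; j <= i; ++j) {
      double s = a[i*d+j];
      for (int k = 0; k < j; ++k) s -= L[i*d+k]*L[j*d+k];
      if (i == j) { if (s <= 0) return; L[i*d+i] = std::sqrt(s); }
      else L[i*d+j] = s / L[j*d+j];
    }
    chol = L;
  }
  void propose(const double *x, double *out, double mult) {
    std::vector<double> z(d);
    for (int i = 0; i < d; ++i) z[i] = norm_rand();
    for (int i = 0; i < d; ++i) {
      double s = 0.0;
      for (int k = 0; k <= i; ++k) s += chol[i*d+k]*z[k];
      out[i] = x[i] + sc * mult * s;
    }
  }
};

// ---------------------------------------------------------------------------
// dynamic-model state

struct Model {
  int S, Tmax;
  NumericMatrix u, yobs;
  LogicalMatrix has;
  NumericVector mal_ini;
  bool use_b, use_g, use_a, shared, hier;
  // hyper-prior constants
  double pa_m, pa_s, pia_a, pia_b;
  double pb_m, pb_s, pib_a, pib_b;
  double pg_m, pg_s, pig_a, pig_b;
  double pk_m, pk_s, pii_a, pii_b;
  double pm_m, pm_s, pnu_a, pnu_b;
  std::vector<double> araw, bet, gam, x0;
  std::vector<double> h; // 0 ta 1 sa 2 tb 3 sb 4 tg 5 sg 6 k 7 si 8 sm 9 nu
  double tconst;
  void update_tconst() {
    tconst = R::lgammafn(0.5*(h[9]+1.0)) - R::lgammafn(0.5*h[9])
           - 0.5*std::log(h[9]*M_PI) - std::log(h[8]);
  }
  inline double st_lpdf(double y, double m) const {
    double z = (y - m) / h[8];
    return tconst - 0.5 * (h[9] + 1.0) * std::log1p(z * z / h[9]);
  }
  int G() const { return shared ? 1 : S; }
  double subj_ll(int i, double ar, double b, double g, double xx0) const {
    double alpha = use_a ? 1.0 / (1.0 + std::exp(-ar)) : 1.0;
    double x = xx0, ll = 0.0;
    for (int t = 0; t < Tmax; ++t) {
      double m = sigmo(x);
      if (has(i, t)) ll += st_lpdf(yobs(i, t), m);
      if (u(i, t) > 0.0) x = alpha * x + (use_b ? b * u(i, t) : 0.0);
      else               x = alpha * x + (use_g ? g * m : 0.0);
    }
    return ll;
  }
  double group_ll(int g) const {
    if (!shared) return subj_ll(g, araw[g], bet[g], gam[g], x0[g]);
    double ll = 0.0;
    for (int i = 0; i < S; ++i) ll += subj_ll(i, araw[0], bet[0], gam[0], h[6]*mal_ini[i]);
    return ll;
  }
  // family fam: 0 alpha, 1 beta, 2 gamma, 3 x0/k -- hyper prior + subject priors
  double fam_lp(int fam) const {
    double lp = 0.0;
    int G_ = G();
    if (fam == 0) {
      if (!use_a) return 0.0;
      if (hier) lp += ldnorm(h[0], pa_m, pa_s) + invgamma_lpdf(h[1], pia_a, pia_b);
      for (int i = 0; i < G_; ++i) lp += ldnorm(araw[i], h[0], h[1]);
    } else if (fam == 1) {
      if (!use_b) return 0.0;
      if (hier) lp += ldnorm(h[2], pb_m, pb_s) + invgamma_lpdf(h[3], pib_a, pib_b);
      double lc = R::pnorm(h[2] / h[3], 0.0, 1.0, 1, 1);
      for (int i = 0; i < G_; ++i) {
        if (bet[i] < 0) return R_NegInf;
        lp += ldnorm(bet[i], h[2], h[3]);
      }
      lp -= G_ * lc;
    } else if (fam == 2) {
      if (!use_g) return 0.0;
      if (hier) lp += ldnorm(h[4], pg_m, pg_s) + invgamma_lpdf(h[5], pig_a, pig_b);
      double lc = R::pnorm(h[4] / h[5], 0.0, 1.0, 1, 1);
      for (int i = 0; i < G_; ++i) {
        if (gam[i] < 0) return R_NegInf;
        lp += ldnorm(gam[i], h[4], h[5]);
      }
      lp -= G_ * lc;
    } else {
      if (hier) lp += tn_lpdf(h[6], pk_m, pk_s);
      if (shared) return lp;
      if (hier) lp += invgamma_lpdf(h[7], pii_a, pii_b);
      for (int i = 0; i < S; ++i) {
        if (x0[i] < 0) return R_NegInf;
        lp += ldnorm(x0[i], h[6]*mal_ini[i], h[7])
            - R::pnorm(h[6]*mal_ini[i]/h[7], 0.0, 1.0, 1, 1);
      }
    }
    return lp;
  }
  double noise_lp() const {
    return R::dgamma(h[9], pnu_a, 1.0/pnu_b, 1) + tn_lpdf(h[8], pm_m, pm_s);
  }
  // subject prior terms without truncation constants (cancel in subject MH)
  double subj_lp_nc(int i) const {
    double lp = 0.0;
    if (use_a) lp += ldnorm(araw[i], h[0], h[1]);
    if (use_b) { if (bet[i] < 0) return R_NegInf; lp += ldnorm(bet[i], h[2], h[3]); }
    if (use_g) { if (gam[i] < 0) return R_NegInf; lp += ldnorm(gam[i], h[4], h[5]); }
    if (!shared) { if (x0[i] < 0) return R_NegInf; lp += ldnorm(x0[i], h[6]*mal_ini[i], h[7]); }
    return lp;
  }
};

// [[Rcpp::export]]
List run_hbdm_chain(List data, List cfg) {
  Model M;
  M.S = as<int>(data["S"]); M.Tmax = as<int>(data["Tmax"]);
  M.u = as<NumericMatrix>(data["u"]); M.yobs = as<NumericMatrix>(data["yobs"]);
  M.has = as<LogicalMatrix>(data["has"]); M.mal_ini = as<NumericVector>(data["mal_ini"]);
  M.use_a = as<bool>(cfg["use_a"]); M.use_b = as<bool>(cfg["use_b"]);
  M.use_g = as<bool>(cfg["use_g"]); M.shared = as<bool>(cfg["shared"]);
  M.hier = as<bool>(cfg["hier"]);
  NumericVector pc = as<NumericVector>(cfg["prior_const"]);
  M.pa_m=pc[0]; M.pa_s=pc[1]; M.pia_a=pc[2]; M.pia_b=pc[3];
  M.pb_m=pc[4]; M.pb_s=pc[5]; M.pib_a=pc[6]; M.pib_b=pc[7];
  M.pg_m=pc[8]; M.pg_s=pc[9]; M.pig_a=pc[10]; M.pig_b=pc[11];
  M.pk_m=pc[12]; M.pk_s=pc[13]; M.pii_a=pc[14]; M.pii_b=pc[15];
  M.pm_m=pc[16]; M.pm_s=pc[17]; M.pnu_a=pc[18]; M.pnu_b=pc[19];
  int warmup = as<int>(cfg["warmup"]), keep = as<int>(cfg["keep"]), thin = as<int>(cfg["thin"]);
  int global_reps = as<int>(cfg["global_reps"]);
  int prior_reps = as<int>(cfg["prior_reps"]);
  NumericVector h0 = as<NumericVector>(cfg["h_init"]);
  M.h.assign(h0.begin(), h0.end());
  M.update_tconst();
  int G = M.G();
  NumericVector s0 = as<NumericVector>(cfg["s_init"]);
  M.araw.assign(G, s0[0]); M.bet.assign(G, s0[1]); M.gam.assign(G, s0[2]);
  M.x0.assign(G, 1.0);
  for (int i = 0; i < G; ++i) M.x0[i] = std::max(0.2, M.h[6] * M.mal_ini[i]);

  int npar_s = 4 * G;
  Adapt ad; ad.init(npar_s + 10 + 8 + G + 5, 0.2);
  std::vector<BlockAM> sam(G); for (int g = 0; g < G; ++g) sam[g].init(4);
  std::vector<BlockAM> ham(4); for (int q = 0; q < 4; ++q) ham[q].init(2);
  BlockAM gam8; gam8.init(8);
  int total = warmup + keep * thin;
  NumericMatrix out(keep, npar_s + 10);
  int row = 0;
  RNGScope scope;
  std::vector<double> llc(G);
  for (int g = 0; g < G; ++g) llc[g] = M.group_ll(g);
  double llsum = 0.0; for (int g = 0; g < G; ++g) llsum += llc[g];

  for (int it = 0; it < total; ++it) {
    // ---- univariate subject RW updates (every sweep in warmup, alternate after)
    for (int g = 0; g < G && (it < warmup || it % 2 == 0); ++g) {
      for (int p = 0; p < 4; ++p) {
        if ((p==0&&!M.use_a)||(p==1&&!M.use_b)||(p==2&&!M.use_g)||(p==3&&M.shared)) continue;
        int j = 4 * g + p;
        double *tgt = (p==0)?&M.araw[g]:(p==1)?&M.bet[g]:(p==2)?&M.gam[g]:&M.x0[g];
        double old = *tgt;
        double prop = old + std::exp(ad.ls[j]) * norm_rand();
        if (p > 0) prop = std::fabs(prop);        // univariate reflection: symmetric
        double lp0 = M.subj_lp_nc(g) + llc[g];
        *tgt = prop;
        double ll1 = M.group_ll(g);
        double lp1 = M.subj_lp_nc(g) + ll1;
        bool acc = std::log(unif_rand()) < lp1 - lp0;
        if (acc) { llsum += ll1 - llc[g]; llc[g] = ll1; } else *tgt = old;
        ad.tick(j, acc);
      }
    }
    if (!M.shared) {
      for (int g = 0; g < G; ++g) {
        // ---- per-subject 4-d adaptive-covariance block
        int j = npar_s + 10 + 8 + g;
        double cur[4] = {M.araw[g], M.bet[g], M.gam[g], M.x0[g]};
        double prop[4];
        sam[g].propose(cur, prop, std::exp(ad.ls[j]));
        bool bad = (M.use_b && prop[1] < 0) || (M.use_g && prop[2] < 0) || prop[3] < 0;
        if (!bad) {
          double lp0 = M.subj_lp_nc(g) + llc[g];
          if (M.use_a) M.araw[g] = prop[0];
          if (M.use_b) M.bet[g] = prop[1];
          if (M.use_g) M.gam[g] = prop[2];
          M.x0[g] = prop[3];
          double ll1 = M.group_ll(g);
          double lp1 = M.subj_lp_nc(g) + ll1;
          bool acc = std::log(unif_rand()) < lp1 - lp0;
          if (acc) { llsum += ll1 - llc[g]; llc[g] = ll1; }
          else { M.araw[g]=cur[0]; M.bet[g]=cur[1]; M.gam[g]=cur[2]; M.x0[g]=cur[3]; }
          ad.tick(j, acc);
        } else ad.tick(j, false);
        double st[4] = {M.araw[g], M.bet[g], M.gam[g], M.x0[g]};
        if (it < warmup) sam[g].push(st);
        // ---- independence proposals from the conditional prior
        for (int rp = 0; rp < prior_reps; ++rp) {
          int p = (int)(unif_rand() * 4.0); if (p > 3) p = 3;
          if ((p==0&&!M.use_a)||(p==1&&!M.use_b)||(p==2&&!M.use_g)) continue;
          double old = (p==0)?M.araw[g]:(p==1)?M.bet[g]:(p==2)?M.gam[g]:M.x0[g];
          double prop2 = (p==0) ? R::rnorm(M.h[0], M.h[1])
                        : (p==1) ? rtnorm0(M.h[2], M.h[3])
                        : (p==2) ? rtnorm0(M.h[4], M.h[5])
                        : rtnorm0(M.h[6]*M.mal_ini[g], M.h[7]);
          double *tgt = (p==0)?&M.araw[g]:(p==1)?&M.bet[g]:(p==2)?&M.gam[g]:&M.x0[g];
          *tgt = prop2;
          double ll1 = M.group_ll(g);
          if (std::log(unif_rand()) < ll1 - llc[g]) { llsum += ll1 - llc[g]; llc[g] = ll1; }
          else *tgt = old;
        }
      }
    }
    if (M.hier && !M.shared) {
      // ---- exact Gibbs for theta_alpha | araw, sigma_alpha
      if (M.use_a) {
        double s2 = M.h[1]*M.h[1];
        double prec = 1.0/(M.pa_s*M.pa_s) + G/s2;
        double sum = 0.0; for (int i = 0; i < G; ++i) sum += M.araw[i];
        M.h[0] = (M.pa_m/(M.pa_s*M.pa_s) + sum/s2)/prec + norm_rand()/std::sqrt(prec);
      }
      // ---- per-family shift/scale group moves (warmup only; the global
      //      move below covers the kept phase)
      for (int gm = 0; gm < 4 && it < warmup; ++gm) {
        bool scl = (it + gm) % 2;
        int mv = 2 * gm + (scl ? 1 : 0);
        if ((gm==0&&!M.use_a)||(gm==1&&!M.use_b)||(gm==2&&!M.use_g)) continue;
        int it_ = 2*gm, is_ = 2*gm+1;
        int j = npar_s + 10 + mv;
        double step = std::exp(ad.ls[j]);
        std::vector<double> *vec = (gm==0)?&M.araw:(gm==1)?&M.bet:(gm==2)?&M.gam:&M.x0;
        std::vector<double> vold = *vec;
        double t_old = M.h[it_], s_old = M.h[is_];
        double t_prop = t_old, s_prop = s_old, ldet = 0.0;
        if (scl) {
          double c = std::exp(step * norm_rand());
          s_prop = s_old * c;
          ldet = (G + 1) * std::log(c);
        } else {
          t_prop = t_old + step * norm_rand();
          if (gm == 3 && t_prop < 0) { ad.tick(j, false); continue; }
        }
        double lp0 = M.fam_lp(gm) + llsum;
        bool ok = true;
        for (int i = 0; i < G; ++i) {
          double mu_old = (gm==3) ? t_old * M.mal_ini[i] : t_old;
          double mu_new = (gm==3) ? t_prop * M.mal_ini[i] : t_prop;
          double nv = mu_new + (s_prop/s_old) * ((*vec)[i] - mu_old);
          if (gm > 0 && nv < 0) { ok = false; break; }
          (*vec)[i] = nv;
        }
        bool acc = false;
        if (ok) {
          M.h[it_] = t_prop; M.h[is_] = s_prop;
          std::vector<double> lln(G); double ll1 = 0.0;
          for (int g = 0; g < G; ++g) { lln[g] = M.group_ll(g); ll1 += lln[g]; }
          double lp1 = M.fam_lp(gm) + ll1;
          acc = std::log(unif_rand()) < lp1 - lp0 + ldet;
          if (acc) { llc = lln; llsum = ll1; }
        }
        if (!acc) { *vec = vold; M.h[it_] = t_old; M.h[is_] = s_old; }
        ad.tick(j, acc);
      }
      // ---- global move on all 8 hierarchy hypers, z-fixed transforms
      for (int rep = 0; rep < global_reps; ++rep) {
        int j = npar_s + 10 + 8 + G + 4;
        double cur[8] = {M.h[0], std::log(M.h[1]), M.h[2], std::log(M.h[3]),
                         M.h[4], std::log(M.h[5]), M.h[6], std::log(M.h[7])};
        double prop[8];
        gam8.propose(cur, prop, std::exp(ad.ls[j]));
        bool bad = (prop[6] < 0);
        if (!M.use_a) { prop[0]=cur[0]; prop[1]=cur[1]; }
        if (!M.use_b) { prop[2]=cur[2]; prop[3]=cur[3]; }
        if (!M.use_g) { prop[4]=cur[4]; prop[5]=cur[5]; }
        if (!bad) {
          double hold[10]; for (int p2=0;p2<10;++p2) hold[p2]=M.h[p2];
          std::vector<double> aold = M.araw, bold = M.bet, gold = M.gam, xold = M.x0;
          double lp0 = M.fam_lp(0)+M.fam_lp(1)+M.fam_lp(2)+M.fam_lp(3) + llsum;
          double ldet = 0.0;
          double hn[8] = {prop[0], std::exp(prop[1]), prop[2], std::exp(prop[3]),
                          prop[4], std::exp(prop[5]), prop[6], std::exp(prop[7])};
          bool ok = true;
          for (int i = 0; i < G && ok; ++i) {
            if (M.use_a) M.araw[i] = hn[0] + (hn[1]/hold[1])*(M.araw[i]-hold[0]);
            if (M.use_b) { M.bet[i] = hn[2] + (hn[3]/hold[3])*(M.bet[i]-hold[2]); if (M.bet[i]<0) ok=false; }
            if (M.use_g) { M.gam[i] = hn[4] + (hn[5]/hold[5])*(M.gam[i]-hold[4]); if (M.gam[i]<0) ok=false; }
            double mu_o = hold[6]*M.mal_ini[i], mu_n = hn[6]*M.mal_ini[i];
            M.x0[i] = mu_n + (hn[7]/hold[7])*(M.x0[i]-mu_o); if (M.x0[i]<0) ok=false;
          }
          bool acc = false;
          if (ok) {
            for (int p2 = 0; p2 < 8; ++p2) M.h[p2] = hn[p2];
            if (M.use_a) ldet += (G+1)*(std::log(hn[1])-std::log(hold[1]));
            if (M.use_b) ldet += (G+1)*(std::log(hn[3])-std::log(hold[3]));
            if (M.use_g) ldet += (G+1)*(std::log(hn[5])-std::log(hold[5]));
            ldet += (G+1)*(std::log(hn[7])-std::log(hold[7]));
            std::vector<double> lln(G); double ll1 = 0.0;
            for (int g = 0; g < G; ++g) { lln[g] = M.group_ll(g); ll1 += lln[g]; }
            double lp1 = M.fam_lp(0)+M.fam_lp(1)+M.fam_lp(2)+M.fam_lp(3) + ll1;
            acc = std::log(unif_rand()) < lp1 - lp0 + ldet;
            if (acc) { llc = lln; llsum = ll1; }
          }
          if (!acc) {
            for (int p2 = 0; p2 < 10; ++p2) M.h[p2] = hold[p2];
            M.araw = aold; M.bet = bold; M.gam = gold; M.x0 = xold;
          }
          ad.tick(j, acc);
        } else ad.tick(j, false);
        double st8[8] = {M.h[0], std::log(M.h[1]), M.h[2], std::log(M.h[3]),
                         M.h[4], std::log(M.h[5]), M.h[6], std::log(M.h[7])};
        if (it < warmup) gam8.push(st8);
      }
      // ---- 2-d adaptive moves on each (theta, log sigma) pair
      for (int q = 0; q < 4; ++q) {
        if ((q==0&&!M.use_a)||(q==1&&!M.use_b)||(q==2&&!M.use_g)) continue;
        int it_ = 2*q, is_ = 2*q+1;
        int j = npar_s + 10 + 8 + G + q;
        double cur[2] = {M.h[it_], std::log(M.h[is_])};
        double prop[2];
        ham[q].propose(cur, prop, std::exp(ad.ls[j]));
        bool bad = (q == 3 && prop[0] < 0);
        if (!bad) {
          double lp0 = M.fam_lp(q);
          double sv0 = M.h[it_], sv1 = M.h[is_];
          M.h[it_] = prop[0]; M.h[is_] = std::exp(prop[1]);
          double lp1 = M.fam_lp(q);
          bool acc = std::log(unif_rand()) < lp1 - lp0 + (prop[1] - cur[1]);
          if (!acc) { M.h[it_] = sv0; M.h[is_] = sv1; }
          ad.tick(j, acc);
        } else ad.tick(j, false);
        double st[2] = {M.h[it_], std::log(M.h[is_])};
        if (it < warmup) ham[q].push(st);
      }
    }
    // ---- univariate hyper updates
    for (int p = 0; p < 10; ++p) {
      if (M.hier) {
        if ((p<2&&!M.use_a)||((p==2||p==3)&&!M.use_b)||((p==4||p==5)&&!M.use_g)) continue;
        if (p==7&&M.shared) continue;
        if (p==0&&!M.shared) continue;   // exact Gibbs above
      } else if (p != 8 && p != 9) continue;
      if (M.shared && p == 7) continue;
      int j = npar_s + p;
      double step = std::exp(ad.ls[j]);
      double old = M.h[p];
      bool logscale = (p==1||p==3||p==5||p==7||p==9);
      double prop, lprop = 0.0;
      if (logscale) { prop = old * std::exp(step * norm_rand()); lprop = std::log(prop/old); }
      else { prop = old + step * norm_rand(); if (p==6||p==8) prop = std::fabs(prop); }
      int fam = (p<2)?0:(p<4)?1:(p<6)?2:(p<8)?3:-1;
      bool need_ll = (p==8||p==9||(p==6&&M.shared));
      double lp0 = (fam>=0 ? M.fam_lp(fam) : M.noise_lp()) + (need_ll ? llsum : 0.0);
      M.h[p] = prop;
      if (p==8||p==9) M.update_tconst();
      double ll1 = 0.0; std::vector<double> lln;
      if (need_ll) { lln.assign(G, 0.0); for (int g=0; g<G; ++g){ lln[g]=M.group_ll(g); ll1+=lln[g]; } }
      double lp1 = (fam>=0 ? M.fam_lp(fam) : M.noise_lp()) + ll1;
      bool acc = std::log(unif_rand()) < lp1 - lp0 + lprop;
      if (acc) { if (need_ll) { llc = lln; llsum = ll1; } }
      else { M.h[p] = old; if (p==8||p==9) M.update_tconst(); }
      ad.tick(j, acc);
    }
    if (it < warmup) {
      if (it % 25 == 24) ad.adapt_now(0.30);
      if (it % 200 == 199) {
        gam8.refresh();
        if (!M.shared) for (int g = 0; g < G; ++g) sam[g].refresh();
        for (int q = 0; q < 4; ++q) ham[q].refresh();
      }
    } else if ((it - warmup) % thin == thin - 1) {
      for (int g = 0; g < G; ++g) {
        out(row, 4*g+0) = M.araw[g]; out(row, 4*g+1) = M.bet[g];
        out(row, 4*g+2) = M.gam[g];  out(row, 4*g+3) = M.shared ? M.h[6] : M.x0[g];
      }
      for (int p = 0; p < 10; ++p) out(row, npar_s + p) = M.h[p];
      row++;
    }
  }
  return List::create(_["draws"] = out);
}

// ---------------------------------------------------------------------------
// static comparator models: m = c_i + d_i * t (linear) or sigmoid(c_i + d_i t)
// (logistic), t in weeks since the subject's first measurement; same
// Student-t observation model and a normal hierarchy on (c_i, d_i).

struct StaticModel {
  int S;
  std::vector<int> obs_start, obs_len;
  std::vector<double> obs_t, obs_y;
  bool logistic;
  // prior constants: theta_c N(m,s), sigma_c IG(a,b), theta_d N(m,s),
  // sigma_d IG(a,b), sigma_mal TN(m,s), nu Gamma(shape, rate)
  double pc_m, pc_s, pic_a, pic_b, pd_m, pd_s, pid_a, pid_b, pm_m, pm_s, pnu_a, pnu_b;
  std::vector<double> cc, dd;
  std::vector<double> h; // 0 tc 1 sc 2 td 3 sd 4 sm 5 nu
  double tconst;
  void update_tconst() {
    tconst = R::lgammafn(0.5*(h[5]+1.0)) - R::lgammafn(0.5*h[5])
           - 0.5*std::log(h[5]*M_PI) - std::log(h[4]);
  }
  inline double st_lpdf(double y, double m) const {
    double z = (y - m) / h[4];
    return tconst - 0.5 * (h[5] + 1.0) * std::log1p(z * z / h[5]);
  }
  double subj_ll(int i, double c, double d) const {
    double ll = 0.0;
    for (int j = obs_start[i]; j < obs_start[i] + obs_len[i]; ++j) {
      double eta = c + d * obs_t[j];
      double m = logistic ? sigmo(eta) : eta;
      ll += st_lpdf(obs_y[j], m);
    }
    return ll;
  }
  double fam_lp(int fam) const {  // 0: c family, 1: d family
    double lp = 0.0;
    if (fam == 0) {
      lp += ldnorm(h[0], pc_m, pc_s) + invgamma_lpdf(h[1], pic_a, pic_b);
      for (int i = 0; i < S; ++i) lp += ldnorm(cc[i], h[0], h[1]);
    } else {
      lp += ldnorm(h[2], pd_m, pd_s) + invgamma_lpdf(h[3], pid_a, pid_b);
      for (int i = 0; i < S; ++i) lp += ldnorm(dd[i], h[2], h[3]);
    }
    return lp;
  }
  double noise_lp() const {
    return R::dgamma(h[5], pnu_a, 1.0/pnu_b, 1) + tn_lpdf(h[4], pm_m, pm_s);
  }
};

// [[Rcpp::export]]
List run_static_chain(List data, List cfg) {
  StaticModel M;
  M.S = as<int>(data["S"]);
  M.obs_start = as<std::vector<int>>(data["obs_start"]);
  M.obs_len = as<std::vector<int>>(data["obs_len"]);
  M.obs_t = as<std::vector<double>>(data["obs_t"]);
  M.obs_y = as<std::vector<double>>(data["obs_y"]);
  M.logistic = as<bool>(cfg["logistic"]);
  NumericVector pc = as<NumericVector>(cfg["prior_const"]);
  M.pc_m=pc[0]; M.pc_s=pc[1]; M.pic_a=pc[2]; M.pic_b=pc[3];
  M.pd_m=pc[4]; M.pd_s=pc[5]; M.pid_a=pc[6]; M.pid_b=pc[7];
  M.pm_m=pc[8]; M.pm_s=pc[9]; M.pnu_a=pc[10]; M.pnu_b=pc[11];
  int warmup = as<int>(cfg["warmup"]), keep = as<int>(cfg["keep"]), thin = as<int>(cfg["thin"]);
  NumericVector h0 = as<NumericVector>(cfg["h_init"]);
  M.h.assign(h0.begin(), h0.end());
  M.update_tconst();
  NumericVector c0 = as<NumericVector>(data["c_init"]);
  M.cc.assign(c0.begin(), c0.end());
  M.dd.assign(M.S, 0.0);
  int npar_s = 2 * M.S;
  Adapt ad; ad.init(npar_s + 6 + M.S + 2, 0.1);
  std::vector<BlockAM> sam(M.S);
  for (int g = 0; g < M.S; ++g) sam[g].init(2);
  int total = warmup + keep * thin;
  NumericMatrix out(keep, npar_s + 6);
  int row = 0;
  RNGScope scope;
  std::vector<double> llc(M.S);
  for (int g = 0; g < M.S; ++g) llc[g] = M.subj_ll(g, M.cc[g], M.dd[g]);
  double llsum = 0.0; for (int g = 0; g < M.S; ++g) llsum += llc[g];

  for (int it = 0; it < total; ++it) {
    for (int g = 0; g < M.S; ++g) {
      for (int p = 0; p < 2; ++p) {
        int j = 2 * g + p;
        double *tgt = p == 0 ? &M.cc[g] : &M.dd[g];
        double old = *tgt;
        double prop = old + std::exp(ad.ls[j]) * norm_rand();
        double mu = p == 0 ? M.h[0] : M.h[2];
        double sd = p == 0 ? M.h[1] : M.h[3];
        double lp0 = ldnorm(old, mu, sd) + llc[g];
        *tgt = prop;
        double ll1 = M.subj_ll(g, M.cc[g], M.dd[g]);
        double lp1 = ldnorm(prop, mu, sd) + ll1;
        bool acc = std::log(unif_rand()) < lp1 - lp0;
        if (acc) { llsum += ll1 - llc[g]; llc[g] = ll1; } else *tgt = old;
        ad.tick(j, acc);
      }
      // 2-d AM block
      int j = npar_s + 6 + g;
      double cur[2] = {M.cc[g], M.dd[g]}, prop[2];
      sam[g].propose(cur, prop, std::exp(ad.ls[j]));
      double lp0 = ldnorm(cur[0], M.h[0], M.h[1]) + ldnorm(cur[1], M.h[2], M.h[3]) + llc[g];
      double ll1 = M.subj_ll(g, prop[0], prop[1]);
      double lp1 = ldnorm(prop[0], M.h[0], M.h[1]) + ldnorm(prop[1], M.h[2], M.h[3]) + ll1;
      bool acc = std::log(unif_rand()) < lp1 - lp0;
      if (acc) { M.cc[g] = prop[0]; M.dd[g] = prop[1]; llsum += ll1 - llc[g]; llc[g] = ll1; }
      ad.tick(j, acc);
      double st[2] = {M.cc[g], M.dd[g]};
      if (it < warmup) sam[g].push(st);
    }
    // exact Gibbs for theta_c, theta_d
    for (int q = 0; q < 2; ++q) {
      double pm = q == 0 ? M.pc_m : M.pd_m, ps = q == 0 ? M.pc_s : M.pd_s;
      double sg = q == 0 ? M.h[1] : M.h[3];
      const std::vector<double> &v = q == 0 ? M.cc : M.dd;
      double sum = 0.0; for (int i = 0; i < M.S; ++i) sum += v[i];
      double prec = 1.0/(ps*ps) + M.S/(sg*sg);
      M.h[q == 0 ? 0 : 2] = (pm/(ps*ps) + sum/(sg*sg))/prec + norm_rand()/std::sqrt(prec);
    }
    // log-RW on sigma_c, sigma_d + group scale moves
    for (int q = 0; q < 2; ++q) {
      int hp = q == 0 ? 1 : 3;
      int j = npar_s + hp;
      double old = M.h[hp];
      double prop = old * std::exp(std::exp(ad.ls[j]) * norm_rand());
      double lp0 = M.fam_lp(q);
      M.h[hp] = prop;
      double lp1 = M.fam_lp(q);
      bool acc = std::log(unif_rand()) < lp1 - lp0 + std::log(prop/old);
      if (!acc) M.h[hp] = old;
      ad.tick(j, acc);
      // z-fixed scale move
      int j2 = npar_s + 6 + M.S + q;
      double c = std::exp(std::exp(ad.ls[j2]) * norm_rand());
      double t0 = M.h[q == 0 ? 0 : 2];
      std::vector<double> &v = q == 0 ? M.cc : M.dd;
      std::vector<double> vold = v;
      double s_old = M.h[hp];
      double lpa = M.fam_lp(q) + llsum;
      for (int i = 0; i < M.S; ++i) v[i] = t0 + c * (v[i] - t0);
      M.h[hp] = s_old * c;
      std::vector<double> lln(M.S); double ll1 = 0.0;
      for (int g = 0; g < M.S; ++g) { lln[g] = M.subj_ll(g, M.cc[g], M.dd[g]); ll1 += lln[g]; }
      double lpb = M.fam_lp(q) + ll1;
      bool acc2 = std::log(unif_rand()) < lpb - lpa + (M.S + 1) * std::log(c);
      if (acc2) { llc = lln; llsum = ll1; }
      else { v = vold; M.h[hp] = s_old; }
      ad.tick(j2, acc2);
    }
    // sigma_mal, nu
    for (int hp = 4; hp <= 5; ++hp) {
      int j = npar_s + hp;
      double old = M.h[hp];
      double prop, lprop = 0.0;
      if (hp == 5) { prop = old * std::exp(std::exp(ad.ls[j]) * norm_rand()); lprop = std::log(prop/old); }
      else { prop = std::fabs(old + std::exp(ad.ls[j]) * norm_rand()); }
      double lp0 = M.noise_lp() + llsum;
      M.h[hp] = prop;
      M.update_tconst();
      std::vector<double> lln(M.S); double ll1 = 0.0;
      for (int g = 0; g < M.S; ++g) { lln[g] = M.subj_ll(g, M.cc[g], M.dd[g]); ll1 += lln[g]; }
      double lp1 = M.noise_lp() + ll1;
      bool acc = std::log(unif_rand()) < lp1 - lp0 + lprop;
      if (acc) { llc = lln; llsum = ll1; }
      else { M.h[hp] = old; M.update_tconst(); }
      ad.tick(j, acc);
    }
    if (it < warmup) {
      if (it % 25 == 24) ad.adapt_now(0.30);
      if (it % 200 == 199) for (int g = 0; g < M.S; ++g) sam[g].refresh();
    } else if ((it - warmup) % thin == thin - 1) {
      for (int g = 0; g < M.S; ++g) { out(row, 2*g) = M.cc[g]; out(row, 2*g+1) = M.dd[g]; }
      for (int p = 0; p < 6; ++p) out(row, npar_s + p) = M.h[p];
      row++;
    }
  }
  return List::create(_["draws"] = out);
}

// ---------------------------------------------------------------------------
// posterior trajectory helpers (dynamic family)

static void draw_traj(const NumericMatrix &draws, int r, int S, int subj,
                      const NumericMatrix &u, const NumericVector &mal_ini,
                      bool use_a, bool use_b, bool use_g, bool shared,
                      int Tmax, double *mout) {
  int g = shared ? 0 : subj;
  double ar = draws(r, 4*g+0), b = draws(r, 4*g+1), gm = draws(r, 4*g+2);
  double alpha = use_a ? 1.0 / (1.0 + std::exp(-ar)) : 1.0;
  double x = shared ? draws(r, 4*g+3) * mal_ini[subj] : draws(r, 4*g+3);
  for (int t = 0; t < Tmax; ++t) {
    double m = sigmo(x);
    mout[t] = m;
    if (u(subj, t) > 0.0) x = alpha * x + (use_b ? b * u(subj, t) : 0.0);
    else                  x = alpha * x + (use_g ? gm * m : 0.0);
  }
}

// posterior draws of the predicted MAL trajectory for one subject
// [[Rcpp::export]]
NumericMatrix m_draws_cpp(NumericMatrix draws, List data, List cfg, int subj) {
  int S = as<int>(data["S"]), Tmax = as<int>(data["Tmax"]);
  NumericMatrix u = as<NumericMatrix>(data["u"]);
  NumericVector mal_ini = as<NumericVector>(data["mal_ini"]);
  bool use_a = as<bool>(cfg["use_a"]), use_b = as<bool>(cfg["use_b"]);
  bool use_g = as<bool>(cfg["use_g"]), shared = as<bool>(cfg["shared"]);
  int n = draws.nrow();
  NumericMatrix out(n, Tmax);
  std::vector<double> buf(Tmax);
  for (int r = 0; r < n; ++r) {
    draw_traj(draws, r, S, subj - 1, u, mal_ini, use_a, use_b, use_g, shared, Tmax, buf.data());
    for (int t = 0; t < Tmax; ++t) out(r, t) = buf[t];
  }
  return out;
}

// pointwise Student-t log-likelihood matrix: draws x observations
// [[Rcpp::export]]
NumericMatrix pointwise_ll_cpp(NumericMatrix draws, List data, List cfg) {
  int S = as<int>(data["S"]), Tmax = as<int>(data["Tmax"]);
  NumericMatrix u = as<NumericMatrix>(data["u"]);
  NumericMatrix yobs = as<NumericMatrix>(data["yobs"]);
  LogicalMatrix has = as<LogicalMatrix>(data["has"]);
  NumericVector mal_ini = as<NumericVector>(data["mal_ini"]);
  bool use_a = as<bool>(cfg["use_a"]), use_b = as<bool>(cfg["use_b"]);
  bool use_g = as<bool>(cfg["use_g"]), shared = as<bool>(cfg["shared"]);
  int n = draws.nrow(), npar = draws.ncol();
  int nobs = 0;
  for (int i = 0; i < S; ++i) for (int t = 0; t < Tmax; ++t) if (has(i, t)) nobs++;
  NumericMatrix out(n, nobs);
  std::vector<double> buf(Tmax);
  for (int r = 0; r < n; ++r) {
    double sm = draws(r, npar - 2), nu = draws(r, npar - 1);
    double tc = R::lgammafn(0.5*(nu+1.0)) - R::lgammafn(0.5*nu)
              - 0.5*std::log(nu*M_PI) - std::log(sm);
    int col = 0;
    for (int i = 0; i < S; ++i) {
      draw_traj(draws, r, S, i, u, mal_ini, use_a, use_b, use_g, shared, Tmax, buf.data());
      for (int t = 0; t < Tmax; ++t) if (has(i, t)) {
        double z = (yobs(i, t) - buf[t]) / sm;
        out(r, col++) = tc - 0.5 * (nu + 1.0) * std::log1p(z * z / nu);
      }
    }
  }
  return out;
}
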