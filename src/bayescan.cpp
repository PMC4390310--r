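// Reversible-jump MCMC for the locus-effect F-model: the population-
// pair differentiation of locus i in population j is decomposed on the
// logistic scale as logit(F_ST,ij) = alpha_i + beta_j; a locus-effect
// alpha_i is toggled in and out of the model by reversible jump and the
// Bayes factor of the with-selection model is the posterior odds over
// the prior odds of inclusion.
//
// Codominant loci enter through the Dirichlet-multinomial likelihood of
// their allele counts; dominant loci carry a latent per-population
// band-absence allele frequency with a binomial phenotype likelihood in
// which the inbreeding coefficient is itself sampled under a uniform
// prior on [0, 1].

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct BayescanData {
  // codominant: counts[l] is a (n_alleles x 2) matrix of allele counts
  std::vector<std::vector<std::vector<double>>> counts;  // [l][a][j]
  std::vector<int> n_all;
  // dominant: x_abs[l][j] band-absent individuals, n_ind[l][j] scored
  std::vector<std::vector<double>> x_abs, n_ind;
  int Lc = 0, Ld = 0;
};

static inline double theta_of(double a, double b) {
  // logit(FST) = a + b;  theta = (1-FST)/FST = exp(-(a+b))
  double t = std::exp(-(a + b));
  if (t < 1e-6) t = 1e-6;
  if (t > 1e8) t = 1e8;
  return t;
}

// Dirichlet-multinomial log-likelihood of locus l in population j,
// given the ancestral frequency vector of that locus
static double ll_cod(const BayescanData& D, const std::vector<double>& pAl,
                     int l, int j, double th) {
  const std::vector<std::vector<double>>& cnt = D.counts[l];
  int A = D.n_all[l];
  double n = 0.0;
  for (int a = 0; a < A; ++a) n += cnt[a][j];
  if (n <= 0) return 0.0;
  double ll = R::lgammafn(th) - R::lgammafn(n + th);
  for (int a = 0; a < A; ++a) {
    double sh = th * pAl[a];
    if (sh < 1e-8) sh = 1e-8;
    ll += R::lgammafn(cnt[a][j] + sh) - R::lgammafn(sh);
  }
  return ll;
}

// dominant: Beta prior of the latent absence-allele frequency q_lj
static double ll_dom_prior(double q, double qA, double th) {
  double s1 = th * qA, s2 = th * (1.0 - qA);
  if (s1 < 1e-8) s1 = 1e-8;
  if (s2 < 1e-8) s2 = 1e-8;
  return R::dbeta(q, s1, s2, 1);
}

static double ll_dom_obs(const BayescanData& D, int l, int j,
                         double q, double fis) {
  double pi = q * q + fis * q * (1.0 - q);
  if (pi < 1e-9) pi = 1e-9;
  if (pi > 1.0 - 1e-9) pi = 1.0 - 1e-9;
  return D.x_abs[l][j] * std::log(pi)
       + (D.n_ind[l][j] - D.x_abs[l][j]) * std::log(1.0 - pi);
}

// [[Rcpp::export]]
List bayescan_rj(List cod_counts, NumericMatrix dom_x, NumericMatrix dom_n,
                 int n_pilot, int pilot_len, int burnin, int n_iter,
                 int thin, double prior_odds) {
  BayescanData D;
  D.Lc = cod_counts.size();
  D.counts.resize(D.Lc);
  D.n_all.resize(D.Lc);
  for (int l = 0; l < D.Lc; ++l) {
    NumericMatrix m = cod_counts[l];  // alleles x 2
    D.n_all[l] = m.nrow();
    D.counts[l].assign(m.nrow(), std::vector<double>(2, 0.0));
    for (int a = 0; a < m.nrow(); ++a)
      for (int j = 0; j < 2; ++j) D.counts[l][a][j] = m(a, j);
  }
  D.Ld = dom_x.nrow();
  D.x_abs.assign(D.Ld, std::vector<double>(2, 0.0));
  D.n_ind.assign(D.Ld, std::vector<double>(2, 0.0));
  for (int l = 0; l < D.Ld; ++l)
    for (int j = 0; j < 2; ++j) {
      D.x_abs[l][j] = dom_x(l, j);
      D.n_ind[l][j] = dom_n(l, j);
    }
  const int L = D.Lc + D.Ld;  // codominant loci first, then dominant

  // --- state ---
  std::vector<double> alpha(L, 0.0), beta(2, -1.0);
  std::vector<int> incl(L, 0);
  std::vector<std::vector<double>> pA(D.Lc);  // codominant ancestral freqs
  for (int l = 0; l < D.Lc; ++l) {
    int A = D.n_all[l];
    pA[l].assign(A, 0.0);
    double tot = 0.0;
    for (int a = 0; a < A; ++a) {
      pA[l][a] = D.counts[l][a][0] + D.counts[l][a][1] + 1.0;
      tot += pA[l][a];
    }
    for (int a = 0; a < A; ++a) pA[l][a] /= tot;
  }
  std::vector<double> qA(D.Ld, 0.5);          // dominant ancestral q
  std::vector<std::vector<double>> qlat(D.Ld, std::vector<double>(2, 0.5));
  for (int l = 0; l < D.Ld; ++l) {
    double s = 0.0;
    for (int j = 0; j < 2; ++j) {
      double phen = (D.x_abs[l][j] + 0.5) / (D.n_ind[l][j] + 1.0);
      qlat[l][j] = std::sqrt(phen);
      s += qlat[l][j];
    }
    qA[l] = std::min(0.98, std::max(0.02, s / 2.0));
  }
  double fis = 0.2;

  // locus-level likelihood at given alpha value (sum over populations)
  auto lik_locus = [&](int l, double a_val) {
    double ll = 0.0;
    if (l < D.Lc) {
      for (int j = 0; j < 2; ++j)
        ll += ll_cod(D, pA[l], l, j, theta_of(a_val, beta[j]));
    } else {
      int ld = l - D.Lc;
      for (int j = 0; j < 2; ++j)
        ll += ll_dom_prior(qlat[ld][j], qA[ld], theta_of(a_val, beta[j]));
    }
    return ll;
  };

  // adaptive proposal scales
  std::vector<double> sd_alpha(L, 0.5), sd_p(L, 60.0);
  double sd_beta = 0.2, sd_q = 0.1, sd_fis = 0.1;
  std::vector<double> rj_mu(L, 0.0), rj_sd(L, 1.0);
  const double p_incl = prior_odds / (1.0 + prior_odds);

  std::vector<double> incl_cnt(L, 0.0), alpha_sum(L, 0.0);
  std::vector<double> fst_sum(L, 0.0);
  int n_samples = 0;

  auto sweep = [&](bool adapt_phase, bool record,
                   std::vector<double>* acc_a, std::vector<double>* try_a,
                   std::vector<double>* pilot_a_sum,
                   std::vector<double>* pilot_a2_sum, int* pilot_n) {
    // -- beta_j (prior N(-1, 1)) --
    for (int j = 0; j < 2; ++j) {
      double bp = beta[j] + R::norm_rand() * sd_beta;
      double lr = -0.5 * ((bp + 1.0) * (bp + 1.0)
                        - (beta[j] + 1.0) * (beta[j] + 1.0));
      for (int l = 0; l < D.Lc; ++l)
        lr += ll_cod(D, pA[l], l, j, theta_of(alpha[l], bp))
            - ll_cod(D, pA[l], l, j, theta_of(alpha[l], beta[j]));
      for (int l = 0; l < D.Ld; ++l)
        lr += ll_dom_prior(qlat[l][j], qA[l],
                           theta_of(alpha[D.Lc + l], bp))
            - ll_dom_prior(qlat[l][j], qA[l],
                           theta_of(alpha[D.Lc + l], beta[j]));
      if (std::log(R::unif_rand()) < lr) beta[j] = bp;
    }
    // -- ancestral frequencies --
    for (int l = 0; l < D.Lc; ++l) {
      int A = D.n_all[l];
      std::vector<double> prop(A), shc(A), shp(A);
      double tot = 0.0;
      for (int a = 0; a < A; ++a) {
        double g = R::rgamma(std::max(1e-8, sd_p[l] * pA[l][a]), 1.0);
        if (g < 1e-12) g = 1e-12;
        prop[a] = g; tot += g;
      }
      for (int a = 0; a < A; ++a) prop[a] /= tot;
      double lr = 0.0;
      for (int j = 0; j < 2; ++j) {
        double th = theta_of(alpha[l], beta[j]);
        lr += ll_cod(D, prop, l, j, th) - ll_cod(D, pA[l], l, j, th);
      }
      // proposal density ratio (Dirichlet centred at current/proposed)
      double lq = 0.0;
      for (int a = 0; a < A; ++a) {
        double shc_a = std::max(1e-8, sd_p[l] * pA[l][a]);
        double shp_a = std::max(1e-8, sd_p[l] * prop[a]);
        lq += (shp_a - 1.0) * std::log(pA[l][a]) - R::lgammafn(shp_a)
            - ((shc_a - 1.0) * std::log(prop[a]) - R::lgammafn(shc_a));
      }
      lr += lq;
      if (std::log(R::unif_rand()) < lr) pA[l] = prop;
    }
    for (int l = 0; l < D.Ld; ++l) {
      double qp = qA[l] + R::norm_rand() * sd_q;
      if (qp > 1e-4 && qp < 1.0 - 1e-4) {
        double lr = 0.0;
        for (int j = 0; j < 2; ++j) {
          double th = theta_of(alpha[D.Lc + l], beta[j]);
          lr += ll_dom_prior(qlat[l][j], qp, th)
              - ll_dom_prior(qlat[l][j], qA[l], th);
        }
        if (std::log(R::unif_rand()) < lr) qA[l] = qp;
      }
      // latent per-population frequencies
      for (int j = 0; j < 2; ++j) {
        double xp = qlat[l][j] + R::norm_rand() * sd_q;
        if (xp <= 1e-5 || xp >= 1.0 - 1e-5) continue;
        double th = theta_of(alpha[D.Lc + l], beta[j]);
        double lr = ll_dom_prior(xp, qA[l], th)
                  - ll_dom_prior(qlat[l][j], qA[l], th)
                  + ll_dom_obs(D, l, j, xp, fis)
                  - ll_dom_obs(D, l, j, qlat[l][j], fis);
        if (std::log(R::unif_rand()) < lr) qlat[l][j] = xp;
      }
    }
    // -- shared inbreeding coefficient (dominant loci), uniform prior --
    if (D.Ld > 0) {
      double fp = fis + R::norm_rand() * sd_fis;
      if (fp > 0.0 && fp < 1.0) {
        double lr = 0.0;
        for (int l = 0; l < D.Ld; ++l)
          for (int j = 0; j < 2; ++j)
            lr += ll_dom_obs(D, l, j, qlat[l][j], fp)
                - ll_dom_obs(D, l, j, qlat[l][j], fis);
        if (std::log(R::unif_rand()) < lr) fis = fp;
      }
    }
    // -- alpha_i: within-model move + reversible jump --
    for (int l = 0; l < L; ++l) {
      if (incl[l]) {
        double ap = alpha[l] + R::norm_rand() * sd_alpha[l];
        double lr = lik_locus(l, ap) - lik_locus(l, alpha[l])
                  - 0.5 * (ap * ap - alpha[l] * alpha[l]);
        if (try_a) (*try_a)[l] += 1.0;
        if (std::log(R::unif_rand()) < lr) {
          alpha[l] = ap;
          if (acc_a) (*acc_a)[l] += 1.0;
        }
        if (pilot_a_sum) {
          (*pilot_a_sum)[l] += alpha[l];
          (*pilot_a2_sum)[l] += alpha[l] * alpha[l];
        }
      }
      // reversible jump
      if (!incl[l]) {
        double ap = rj_mu[l] + R::norm_rand() * rj_sd[l];
        double lprop = R::dnorm(ap, rj_mu[l], rj_sd[l], 1);
        double lprior = R::dnorm(ap, 0.0, 1.0, 1);
        double lr = lik_locus(l, ap) - lik_locus(l, 0.0)
                  + lprior - lprop
                  + std::log(p_incl / (1.0 - p_incl));
        if (std::log(R::unif_rand()) < lr) { incl[l] = 1; alpha[l] = ap; }
      } else {
        double ap = alpha[l];
        double lprop = R::dnorm(ap, rj_mu[l], rj_sd[l], 1);
        double lprior = R::dnorm(ap, 0.0, 1.0, 1);
        double lr = lik_locus(l, 0.0) - lik_locus(l, ap)
                  + lprop - lprior
                  + std::log((1.0 - p_incl) / p_incl);
        if (std::log(R::unif_rand()) < lr) { incl[l] = 0; alpha[l] = 0.0; }
      }
    }
    if (pilot_n) *pilot_n += 1;
    if (record) {
      for (int l = 0; l < L; ++l) {
        incl_cnt[l] += incl[l];
        alpha_sum[l] += alpha[l];
        double fst = 0.0;
        for (int j = 0; j < 2; ++j)
          fst += 1.0 / (1.0 + theta_of(alpha[l], beta[j]));
        fst_sum[l] += fst / 2.0;
      }
      n_samples += 1;
    }
  };

  // --- pilot runs: adapt proposal scales with all loci included ---
  std::fill(incl.begin(), incl.end(), 1);
  for (int p = 0; p < n_pilot; ++p) {
    std::vector<double> acc(L, 0.0), tries(L, 0.0);
    std::vector<double> asum(L, 0.0), a2sum(L, 0.0);
    int pn = 0;
    for (int it = 0; it < pilot_len; ++it)
      sweep(true, false, &acc, &tries, &asum, &a2sum, &pn);
    for (int l = 0; l < L; ++l) {
      if (tries[l] > 0) {
        double rate = acc[l] / tries[l];
        if (rate < 0.25) sd_alpha[l] *= 0.8;
        else if (rate > 0.45) sd_alpha[l] *= 1.25;
        sd_alpha[l] = std::min(3.0, std::max(0.05, sd_alpha[l]));
      }
      if (pn > 1) {
        double mu = asum[l] / pn;
        double v = a2sum[l] / pn - mu * mu;
        rj_mu[l] = mu;
        rj_sd[l] = std::max(0.3, std::sqrt(std::max(0.0, v)) * 2.0);
      }
    }
  }
  // reset to the prior inclusion state for the main run
  std::fill(incl.begin(), incl.end(), 0);
  std::fill(alpha.begin(), alpha.end(), 0.0);

  for (int it = 0; it < burnin; ++it)
    sweep(false, false, nullptr, nullptr, nullptr, nullptr, nullptr);
  for (int it = 0; it < n_iter; ++it) {
    bool record = (it % thin) == 0;
    sweep(false, record, nullptr, nullptr, nullptr, nullptr, nullptr);
  }

  NumericVector post_incl(L), post_alpha(L), post_fst(L);
  for (int l = 0; l < L; ++l) {
    post_incl[l] = incl_cnt[l] / n_samples;
    post_alpha[l] = alpha_sum[l] / n_samples;
    post_fst[l] = fst_sum[l] / n_samples;
  }
  return List::create(_["post_incl"] = post_incl,
                      _["post_alpha"] = post_alpha,
                      _["post_fst"] = post_fst,
                      _["n_samples"] = n_samples,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["fis"] = fis);
}
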