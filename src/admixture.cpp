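// Gibbs sampler for model-based admixture clustering with correlated
// cluster allele frequencies (F-model) and mixed marker systems:
// codominant loci contribute both allele copies directly; dominant
// band-present phenotypes carry a latent genotype (heterozygote vs
// presence homozygote) that is integrated by sampling each sweep.
// All randomness goes through R's RNG so set.seed() controls the chain.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void rdirichlet(const std::vector<double>& shape,
                       std::vector<double>& out) {
  double tot = 0.0;
  for (size_t a = 0; a < shape.size(); ++a) {
    double g = R::rgamma(shape[a] > 1e-8 ? shape[a] : 1e-8, 1.0);
    if (g < 1e-12) g = 1e-12;
    out[a] = g;
    tot += g;
  }
  for (size_t a = 0; a < shape.size(); ++a) out[a] /= tot;
}

static double log_dirichlet(const std::vector<double>& x,
                            const std::vector<double>& shape) {
  double s = 0.0, sumsh = 0.0;
  for (size_t a = 0; a < x.size(); ++a) {
    double sh = shape[a] > 1e-8 ? shape[a] : 1e-8;
    s += (sh - 1.0) * std::log(x[a]) - R::lgammafn(sh);
    sumsh += sh;
  }
  return s + R::lgammafn(sumsh);
}

// [[Rcpp::export]]
List admix_gibbs(IntegerMatrix cod1, IntegerMatrix cod2,
                 IntegerVector n_alleles, IntegerMatrix dom,
                 int K, int burnin, int nkeep, double alpha0) {
  const int N = std::max(cod1.nrow(), dom.nrow());
  const int Lc = cod1.ncol();
  const int Ld = dom.ncol();
  if (K < 1) stop("K must be at least 1");
  if (K > N) stop("K exceeds the number of individuals");

  // --- state ---
  // q[i][k]; cluster freqs pc[k][l][a] (codominant), pd[k][l][a in 0/1]
  // (dominant; index = allele code 0=absence, 1=presence); ancestral
  // frequencies pAc, pAd; per-cluster drift F_k; admixture alpha.
  std::vector<std::vector<double>> q(N, std::vector<double>(K, 1.0 / K));
  std::vector<std::vector<std::vector<double>>> pc(K), cc(K);
  std::vector<std::vector<std::vector<double>>> pAc(1);
  pAc[0].resize(Lc);
  for (int l = 0; l < Lc; ++l) {
    int A = n_alleles[l];
    std::vector<double> init(A, 1.0 / A);
    // initialise ancestral freqs from observed counts
    std::vector<double> cnt(A, 1.0);
    for (int i = 0; i < N; ++i) {
      if (cod1(i, l) >= 0) { cnt[cod1(i, l)] += 1; cnt[cod2(i, l)] += 1; }
    }
    double tot = 0; for (int a = 0; a < A; ++a) tot += cnt[a];
    for (int a = 0; a < A; ++a) init[a] = cnt[a] / tot;
    pAc[0][l] = init;
  }
  std::vector<std::vector<double>> pAd(Ld, std::vector<double>(2, 0.5));
  for (int l = 0; l < Ld; ++l) {
    double pres = 1.0, tot = 2.0;  // +1/+1 pseudo-counts
    for (int i = 0; i < N; ++i) {
      if (dom(i, l) >= 0) { tot += 1; if (dom(i, l) == 1) pres += 0.75; }
    }
    // crude initial allele-frequency guess from phenotype frequency
    double phen = pres / tot;
    double p = 1.0 - std::sqrt(std::max(1e-4, 1.0 - phen));
    pAd[l][1] = p; pAd[l][0] = 1.0 - p;
  }
  for (int k = 0; k < K; ++k) {
    pc[k].resize(Lc); cc[k].resize(Lc);
    for (int l = 0; l < Lc; ++l) {
      pc[k][l] = pAc[0][l];
      cc[k][l].assign(n_alleles[l], 0.0);
    }
  }
  std::vector<std::vector<std::vector<double>>> pdk(K), cd(K);
  for (int k = 0; k < K; ++k) {
    pdk[k].resize(Ld); cd[k].resize(Ld);
    for (int l = 0; l < Ld; ++l) { pdk[k][l] = pAd[l]; cd[k][l].assign(2, 0.0); }
  }
  std::vector<double> Fk(K, 0.1);
  double alpha = alpha0;

  std::vector<std::vector<double>> nik(N, std::vector<double>(K, 0.0));
  std::vector<std::vector<double>> qsum(N, std::vector<double>(K, 0.0));
  NumericVector ll_trace(burnin + nkeep);
  std::vector<double> wk(K);

  const int nsweep = burnin + nkeep;
  for (int sw = 0; sw < nsweep; ++sw) {
    // 1. latent assignments ------------------------------------------
    for (int i = 0; i < N; ++i) std::fill(nik[i].begin(), nik[i].end(), 0.0);
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < Lc; ++l) std::fill(cc[k][l].begin(), cc[k][l].end(), 0.0);
      for (int l = 0; l < Ld; ++l) { cd[k][l][0] = 0.0; cd[k][l][1] = 0.0; }
    }
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < Lc; ++l) {
        int a1 = cod1(i, l), a2 = cod2(i, l);
        if (a1 < 0) continue;
        for (int copy = 0; copy < 2; ++copy) {
          int a = copy == 0 ? a1 : a2;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) { wk[k] = q[i][k] * pc[k][l][a]; tot += wk[k]; }
          double u = R::unif_rand() * tot, acc = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) { acc += wk[k]; if (u <= acc) { z = k; break; } }
          nik[i][z] += 1.0;
          cc[z][l][a] += 1.0;
        }
      }
      for (int l = 0; l < Ld; ++l) {
        int y = dom(i, l);
        if (y < 0) continue;
        if (y == 0) {
          // band absent: both copies carry the absence allele
          for (int copy = 0; copy < 2; ++copy) {
            double tot = 0.0;
            for (int k = 0; k < K; ++k) { wk[k] = q[i][k] * pdk[k][l][0]; tot += wk[k]; }
            double u = R::unif_rand() * tot, acc = 0.0;
            int z = K - 1;
            for (int k = 0; k < K; ++k) { acc += wk[k]; if (u <= acc) { z = k; break; } }
            nik[i][z] += 1.0;
            cd[z][l][0] += 1.0;
          }
        } else {
          // band present: sample (z1,a1,z2,a2) jointly, excluding the
          // double-absence configuration
          double w0 = 0.0, w1 = 0.0;
          for (int k = 0; k < K; ++k) {
            w0 += q[i][k] * pdk[k][l][0];
            w1 += q[i][k] * pdk[k][l][1];
          }
          double tot = (w0 + w1) * (w0 + w1) - w0 * w0;
          double u = R::unif_rand() * tot;
          int a1, a2;
          if (u <= w1 * w1) { a1 = 1; a2 = 1; }
          else if (u <= w1 * w1 + w1 * w0) { a1 = 1; a2 = 0; }
          else { a1 = 0; a2 = 1; }
          for (int copy = 0; copy < 2; ++copy) {
            int a = copy == 0 ? a1 : a2;
            double t2 = 0.0;
            for (int k = 0; k < K; ++k) { wk[k] = q[i][k] * pdk[k][l][a]; t2 += wk[k]; }
            double u2 = R::unif_rand() * t2, acc = 0.0;
            int z = K - 1;
            for (int k = 0; k < K; ++k) { acc += wk[k]; if (u2 <= acc) { z = k; break; } }
            nik[i][z] += 1.0;
            cd[z][l][a] += 1.0;
          }
        }
      }
    }
    // 2. q | z ------------------------------------------------------
    for (int i = 0; i < N; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + nik[i][k], 1.0);
        if (g < 1e-12) g = 1e-12;
        q[i][k] = g; tot += g;
      }
      for (int k = 0; k < K; ++k) q[i][k] /= tot;
    }
    // 3. cluster frequencies | counts, F-model prior ----------------
    std::vector<double> shape;
    for (int k = 0; k < K; ++k) {
      double theta = (1.0 - Fk[k]) / Fk[k];
      for (int l = 0; l < Lc; ++l) {
        int A = n_alleles[l];
        shape.assign(A, 0.0);
        for (int a = 0; a < A; ++a) shape[a] = theta * pAc[0][l][a] + cc[k][l][a];
        rdirichlet(shape, pc[k][l]);
      }
      for (int l = 0; l < Ld; ++l) {
        shape.assign(2, 0.0);
        for (int a = 0; a < 2; ++a) shape[a] = theta * pAd[l][a] + cd[k][l][a];
        rdirichlet(shape, pdk[k][l]);
      }
    }
    // 4. ancestral frequencies: Dirichlet-proposal MH ---------------
    const double conc = 60.0;
    for (int l = 0; l < Lc; ++l) {
      int A = n_alleles[l];
      std::vector<double> cur = pAc[0][l], prop(A), shc(A), shp(A);
      for (int a = 0; a < A; ++a) shc[a] = conc * cur[a];
      rdirichlet(shc, prop);
      for (int a = 0; a < A; ++a) shp[a] = conc * prop[a];
      double lr = 0.0;
      for (int k = 0; k < K; ++k) {
        double theta = (1.0 - Fk[k]) / Fk[k];
        std::vector<double> sc(A), sp(A);
        for (int a = 0; a < A; ++a) { sc[a] = theta * cur[a]; sp[a] = theta * prop[a]; }
        lr += log_dirichlet(pc[k][l], sp) - log_dirichlet(pc[k][l], sc);
      }
      lr += log_dirichlet(cur, shp) - log_dirichlet(prop, shc);
      if (std::log(R::unif_rand()) < lr) pAc[0][l] = prop;
    }
    for (int l = 0; l < Ld; ++l) {
      std::vector<double> cur = pAd[l], prop(2), shc(2), shp(2);
      shc[0] = conc * cur[0]; shc[1] = conc * cur[1];
      rdirichlet(shc, prop);
      shp[0] = conc * prop[0]; shp[1] = conc * prop[1];
      double lr = 0.0;
      for (int k = 0; k < K; ++k) {
        double theta = (1.0 - Fk[k]) / Fk[k];
        std::vector<double> sc(2), sp(2);
        for (int a = 0; a < 2; ++a) { sc[a] = theta * cur[a]; sp[a] = theta * prop[a]; }
        lr += log_dirichlet(pdk[k][l], sp) - log_dirichlet(pdk[k][l], sc);
      }
      lr += log_dirichlet(cur, shp) - log_dirichlet(prop, shc);
      if (std::log(R::unif_rand()) < lr) pAd[l] = prop;
    }
    // 5. F_k: logit random walk, uniform(0,1) prior -----------------
    for (int k = 0; k < K; ++k) {
      double x = std::log(Fk[k] / (1.0 - Fk[k]));
      double xp = x + R::norm_rand() * 0.25;
      double Fp = 1.0 / (1.0 + std::exp(-xp));
      if (Fp < 1e-4) Fp = 1e-4;
      if (Fp > 0.999) Fp = 0.999;
      double thc = (1.0 - Fk[k]) / Fk[k], thp = (1.0 - Fp) / Fp;
      double lr = 0.0;
      for (int l = 0; l < Lc; ++l) {
        int A = n_alleles[l];
        std::vector<double> sc(A), sp(A);
        for (int a = 0; a < A; ++a) {
          sc[a] = thc * pAc[0][l][a]; sp[a] = thp * pAc[0][l][a];
        }
        lr += log_dirichlet(pc[k][l], sp) - log_dirichlet(pc[k][l], sc);
      }
      for (int l = 0; l < Ld; ++l) {
        std::vector<double> sc(2), sp(2);
        for (int a = 0; a < 2; ++a) {
          sc[a] = thc * pAd[l][a]; sp[a] = thp * pAd[l][a];
        }
        lr += log_dirichlet(pdk[k][l], sp) - log_dirichlet(pdk[k][l], sc);
      }
      // Jacobian of the logit transform under the uniform prior
      lr += std::log(Fp * (1.0 - Fp)) - std::log(Fk[k] * (1.0 - Fk[k]));
      if (std::log(R::unif_rand()) < lr) Fk[k] = Fp;
    }
    // 6. alpha: shared admixture parameter, uniform(0,10) prior -----
    if (K > 1) {
      double ap = alpha + R::norm_rand() * 0.1;
      if (ap > 1e-3 && ap < 10.0) {
        double lr = 0.0;
        for (int i = 0; i < N; ++i) {
          for (int k = 0; k < K; ++k)
            lr += (ap - alpha) * std::log(q[i][k]);
          lr += R::lgammafn(K * ap) - K * R::lgammafn(ap)
              - (R::lgammafn(K * alpha) - K * R::lgammafn(alpha));
        }
        if (std::log(R::unif_rand()) < lr) alpha = ap;
      }
    }
    // 7. log-likelihood of the data given (q, p) --------------------
    double ll = 0.0;
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < Lc; ++l) {
        int a1 = cod1(i, l), a2 = cod2(i, l);
        if (a1 < 0) continue;
        double m1 = 0.0, m2 = 0.0;
        for (int k = 0; k < K; ++k) {
          m1 += q[i][k] * pc[k][l][a1];
          m2 += q[i][k] * pc[k][l][a2];
        }
        ll += (a1 == a2) ? std::log(m1 * m2) : std::log(2.0 * m1 * m2);
      }
      for (int l = 0; l < Ld; ++l) {
        int y = dom(i, l);
        if (y < 0) continue;
        double m0 = 0.0;
        for (int k = 0; k < K; ++k) m0 += q[i][k] * pdk[k][l][0];
        ll += (y == 0) ? 2.0 * std::log(m0) : std::log(1.0 - m0 * m0);
      }
    }
    ll_trace[sw] = ll;
    if (sw >= burnin)
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) qsum[i][k] += q[i][k];
  }

  NumericMatrix qmean(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) qmean(i, k) = qsum[i][k] / nkeep;

  // model-evidence proxy: mean - var/2 of the post-burn-in trace
  double mu = 0.0, vv = 0.0;
  for (int sw = burnin; sw < nsweep; ++sw) mu += ll_trace[sw];
  mu /= nkeep;
  for (int sw = burnin; sw < nsweep; ++sw)
    vv += (ll_trace[sw] - mu) * (ll_trace[sw] - mu);
  vv /= std::max(1, nkeep - 1);
  double lnPD = mu - vv / 2.0;

  return List::create(_["q"] = qmean, _["loglik"] = ll_trace,
                      _["lnPD"] = lnPD, _["alpha"] = alpha,
                      _["F"] = NumericVector(Fk.begin(), Fk.end()));
}
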