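// Single-site Gibbs / Metropolis-Hastings sampler for the Bayesian-alphabet
// whole-genome regression models (BayesA, BayesB, BayesC, BayesCpi).
//
// Model: y = X b + Z (u .* delta) + e, centered-ten genotype coding.
// Uses R's RNG throughout so set.seed() in R gives bit-identical chains.
// The locus loop works on raw column pointers: no per-locus temporaries.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double rchisq1(double df) { return R::rchisq(df); }

// marginal log-likelihood of the single-locus statistic r ~ N(0, v)
static inline double loglik_r(double r, double v) {
  return -0.5 * std::log(v) - 0.5 * r * r / v;
}

static inline double dot_ptr(const double* z, const double* e, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += z[i] * e[i];
  return s;
}

// [[Rcpp::export(name = ".chain_cpp")]]
List chain_cpp(const arma::vec& y, const arma::mat& Z, const arma::mat& X,
               int model,            // 0=A, 1=B, 2=C, 3=Cpi
               double pi0, double ve_start,
               int chain_length, int burn_in, int mh_cycles,
               double nu_a, double nu_e, bool update_variances,
               double Sa, double Se, int check_every) {
  const int n = Z.n_rows, k = Z.n_cols, p = X.n_cols;
  const double prior_mean_a = Sa * nu_a / (nu_a - 2.0);

  arma::vec zz(k), colv(k);
  for (int j = 0; j < k; ++j) {
    zz(j) = arma::dot(Z.col(j), Z.col(j));
    colv(j) = arma::var(Z.col(j));
  }

  arma::vec u(k, arma::fill::zeros);
  arma::ivec delta(k);
  arma::vec s2u(k); s2u.fill(prior_mean_a);   // per-locus (A/B)
  double s2u_common = prior_mean_a;           // common (C/Cpi)
  double sigma2e = ve_start;
  double pi_c = pi0;
  arma::vec b(p, arma::fill::zeros);
  // start all loci in the model (u = 0 so the bookkeeping identity holds)
  delta.fill(1);
  if (model == 1 && pi0 >= 1.0) delta.fill(0);

  arma::mat XtX, Rchol;
  if (p > 0) {
    XtX = X.t() * X;
    Rchol = arma::chol(XtX);  // upper: Rchol' * Rchol = XtX
  }

  arma::vec e = y;            // u = 0, b = 0 at start
  arma::vec g(n, arma::fill::zeros);

  const int n_keep = chain_length - burn_in;
  arma::vec u_sum(k, arma::fill::zeros), d_sum(k, arma::fill::zeros);
  arma::vec b_sum(p, arma::fill::zeros);
  arma::vec va_s(n_keep), ve_s(n_keep), h2_s(n_keep), pi_s(n_keep),
            vam_s(n_keep);
  double mh_acc = 0.0, mh_try = 0.0, book_err = 0.0;

  for (int t = 0; t < chain_length; ++t) {
    // ---- fixed effects: block draw, flat prior ----
    if (p > 0) {
      arma::vec rhs = X.t() * e + XtX * b;
      arma::vec mean = arma::solve(XtX, rhs, arma::solve_opts::likely_sympd);
      arma::vec zn(p);
      for (int i = 0; i < p; ++i) zn(i) = norm_rand();
      arma::vec b_new = mean +
        std::sqrt(sigma2e) * arma::solve(arma::trimatu(Rchol), zn);
      e += X * (b - b_new);
      b = b_new;
    }

    // ---- marker loci, storage order ----
    double* eptr = e.memptr();
    double* gptr = g.memptr();
    for (int j = 0; j < k; ++j) {
      const double zzj = zz(j);
      if (zzj <= 0.0) { u(j) = 0.0; delta(j) = 0; continue; }
      const double* zj = Z.colptr(j);
      const double r = dot_ptr(zj, eptr, n) + zzj * u(j);
      double u_new = 0.0;

      if (model == 0) {                         // BayesA: always in
        const double denom = zzj + sigma2e / s2u(j);
        u_new = r / denom + norm_rand() * std::sqrt(sigma2e / denom);
        delta(j) = 1;
        if (update_variances)
          s2u(j) = (nu_a * Sa + u_new * u_new) / rchisq1(nu_a + 1.0);
      } else if (model == 2 || model == 3) {    // BayesC / BayesCpi
        int d_new = 1;
        if (pi_c > 0.0) {
          const double pic = std::min(std::max(pi_c, 1e-8), 1.0 - 1e-8);
          const double v0 = zzj * sigma2e;
          const double v1 = v0 + zzj * zzj * s2u_common;
          const double logodds = std::log((1.0 - pic) / pic) +
            0.5 * std::log(v0 / v1) + 0.5 * r * r * (1.0 / v0 - 1.0 / v1);
          const double pr = 1.0 / (1.0 + std::exp(-logodds));
          d_new = (unif_rand() < pr) ? 1 : 0;
        }
        if (d_new == 1) {
          const double denom = zzj + sigma2e / s2u_common;
          u_new = r / denom + norm_rand() * std::sqrt(sigma2e / denom);
        }
        delta(j) = d_new;
      } else {                                  // BayesB: MH on (delta, s2)
        int d_cur = delta(j);
        double s2_cur = s2u(j);
        double ll_cur = loglik_r(r, zzj * sigma2e +
                                 d_cur * zzj * zzj * s2_cur);
        for (int c = 0; c < mh_cycles; ++c) {
          const int d_prop = (unif_rand() < (1.0 - pi0)) ? 1 : 0;
          const double s2_prop = update_variances
            ? nu_a * Sa / rchisq1(nu_a) : s2_cur;
          const double ll_prop = loglik_r(r, zzj * sigma2e +
                                          d_prop * zzj * zzj * s2_prop);
          mh_try += 1.0;
          if (std::log(unif_rand()) < ll_prop - ll_cur) {
            d_cur = d_prop; s2_cur = s2_prop; ll_cur = ll_prop;
            mh_acc += 1.0;
          }
        }
        if (d_cur == 1) {
          const double denom = zzj + sigma2e / s2_cur;
          u_new = r / denom + norm_rand() * std::sqrt(sigma2e / denom);
          if (update_variances)
            s2_cur = (nu_a * Sa + u_new * u_new) / rchisq1(nu_a + 1.0);
        }
        delta(j) = d_cur;
        s2u(j) = s2_cur;
      }

      const double diff = u(j) - u_new;   // u(j) is 0 when excluded
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) {
          eptr[i] += zj[i] * diff;
          gptr[i] -= zj[i] * diff;
        }
      }
      u(j) = u_new;
    }

    const int m = arma::accu(delta);

    // ---- common SNP variance (BayesC / BayesCpi) ----
    if ((model == 2 || model == 3) && update_variances)
      s2u_common = (nu_a * Sa + arma::dot(u, u)) / rchisq1(nu_a + m);

    // ---- pi (BayesCpi) ----
    if (model == 3)
      pi_c = R::rbeta((double)(k - m) + 1.0, (double)m + 1.0);

    // ---- residual variance ----
    if (update_variances)
      sigma2e = (arma::dot(e, e) + nu_e * Se) / rchisq1(nu_e + n);

    // ---- genomic variance samples ----
    // realized: spread of the current genomic values across animals;
    // model-implied: effect variance times summed genotype column variance
    // over included loci (free of the Monte Carlo spread of u)
    const double va = (n > 1) ? arma::var(g) : 0.0;
    double va_model = 0.0;
    if (model == 0 || model == 1) {
      for (int j = 0; j < k; ++j) if (delta(j)) va_model += s2u(j) * colv(j);
    } else {
      for (int j = 0; j < k; ++j) if (delta(j)) va_model += colv(j);
      va_model *= s2u_common;
    }
    const double h2 = (va_model + sigma2e > 0.0)
      ? va_model / (va_model + sigma2e) : 0.0;

    if (check_every > 0 && (t + 1) % check_every == 0) {
      arma::vec e_true = y - g;
      if (p > 0) e_true -= X * b;
      const double err = arma::abs(e - e_true).max();
      if (err > book_err) book_err = err;
    }

    if (t >= burn_in) {
      const int s = t - burn_in;
      u_sum += u;                       // excluded loci contribute 0
      for (int j = 0; j < k; ++j) d_sum(j) += delta(j);
      if (p > 0) b_sum += b;
      va_s(s) = va; vam_s(s) = va_model; ve_s(s) = sigma2e;
      h2_s(s) = h2; pi_s(s) = pi_c;
    }
  }

  return List::create(
    _["u_mean"] = u_sum / n_keep,
    _["inclusion"] = d_sum / n_keep,
    _["b_mean"] = (p > 0) ? (b_sum / n_keep) : arma::vec(),
    _["Va_samples"] = vam_s, _["Va_realized_samples"] = va_s,
    _["Ve_samples"] = ve_s,
    _["h2_samples"] = h2_s, _["pi_samples"] = pi_s,
    _["mh_acceptance"] = (mh_try > 0.0) ? mh_acc / mh_try : NA_REAL,
    _["bookkeeping_max_err"] = book_err);
}
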