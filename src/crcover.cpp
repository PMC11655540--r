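// Hidden-state machinery for the register capture-recapture model.
//
// Latent states per individual-year: 0 = present, 1 = absent, 2 = dead.
// Mask codes:                        0 = free, 1 = forced present,
//                                    2 = forced absent, 3 = forced dead.
//
// The yearly transition factorizes as survival-then-movement:
//   present -> {dead: 1-phi, present: phi*psi, absent: phi*(1-psi)}
//   absent  -> {dead: 1-phi, present: phi*eta, absent: phi*(1-eta)}
//   dead    -> dead.
// Emissions given the (prev, now) state pair and the year's record
// (list indicators collapsed to pdet = prod_l theta^o (1-theta)^(1-o),
//  de-registration flag e, recorded-death flag d):
//   now = present: requires e = 0, d = 0; probability pdet
//   present -> absent: all lists zero, d = 0; lambda^e (1-lambda)^(1-e)
//   absent  -> absent: all-zero record only
//   present -> dead: death is recorded (d = 1), nothing else
//   absent/dead -> dead: unrecorded (d = 0), all-zero record.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double inv_logit(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Combined transition x emission matrix for one year, row-major 3x3:
// M[3*s + t] = P(state t, record | state s at previous year).
static inline void row_M(double f, double p, double h, double l, double pd,
                         int ao, int e, int d, double* M) {
  const double emP  = (e == 0 && d == 0) ? pd : 0.0;
  const double emAP = (ao == 0 && d == 0) ? (e ? l : 1.0 - l) : 0.0;
  const double emAA = (ao == 0 && d == 0 && e == 0) ? 1.0 : 0.0;
  const double emDP = (ao == 0 && e == 0 && d == 1) ? 1.0 : 0.0;
  const double emDO = (ao == 0 && e == 0 && d == 0) ? 1.0 : 0.0;
  M[0] = f * p * emP;         M[1] = f * (1.0 - p) * emAP; M[2] = (1.0 - f) * emDP;
  M[3] = f * h * emP;         M[4] = f * (1.0 - h) * emAA; M[5] = (1.0 - f) * emDO;
  M[6] = 0.0;                 M[7] = 0.0;                  M[8] = emDO;
}

// Mask 2 ("forced absent") means known-not-present: the absent state is
// certain at the de-registration year itself (the e = 1 emission already
// rules out presence and death there), but later span years admit an
// unrecorded death abroad, so only the present state is excluded.
static inline void apply_mask(int m, double& nP, double& nA, double& nD) {
  if (m == 1)      { nA = 0.0; nD = 0.0; }
  else if (m == 2) { nP = 0.0; }
  else if (m == 3) { nP = 0.0; nA = 0.0; }
}

// Scaled forward pass over one individual's contiguous rows.
// Returns the log marginal likelihood (-Inf if the record is impossible
// under the mask).  If alpha != nullptr, stores the scaled forward
// probabilities (row-major, 3 per year) for the backward pass.
static double forward_one(int n, const double* phi, const double* psi,
                          const double* eta, const double* lam,
                          const double* pdet, const int* ao, const int* ev,
                          const int* dv, const int* mask, double* alpha) {
  double aP = (ev[0] == 0 && dv[0] == 0) ? pdet[0] : 0.0, aA = 0.0, aD = 0.0;
  if (mask[0] == 2 || mask[0] == 3) aP = 0.0;  // registration year is present
  if (!(aP > 0.0)) return R_NegInf;
  double ll = std::log(aP);
  aP = 1.0;
  if (alpha) { alpha[0] = 1.0; alpha[1] = 0.0; alpha[2] = 0.0; }
  double M[9];
  for (int j = 1; j < n; ++j) {
    row_M(phi[j], psi[j], eta[j], lam[j], pdet[j], ao[j], ev[j], dv[j], M);
    double nP = aP * M[0] + aA * M[3];
    double nA = aP * M[1] + aA * M[4];
    double nD = aP * M[2] + aA * M[5] + aD * M[8];
    apply_mask(mask[j], nP, nA, nD);
    const double c = nP + nA + nD;
    if (!(c > 0.0)) return R_NegInf;
    ll += std::log(c);
    aP = nP / c; aA = nA / c; aD = nD / c;
    if (alpha) { alpha[3 * j] = aP; alpha[3 * j + 1] = aA; alpha[3 * j + 2] = aD; }
  }
  return ll;
}

// Forward-backward smoothing for one individual; fills gamma (row-major,
// 3 per year) with P(state | whole record).  Returns the log-likelihood.
static double fb_one(int n, const double* phi, const double* psi,
                     const double* eta, const double* lam, const double* pdet,
                     const int* ao, const int* ev, const int* dv,
                     const int* mask, double* alpha, double* gamma) {
  const double ll = forward_one(n, phi, psi, eta, lam, pdet, ao, ev, dv, mask, alpha);
  if (!R_FINITE(ll)) return ll;
  double bP = 1.0, bA = 1.0, bD = 1.0;
  gamma[3 * (n - 1)]     = alpha[3 * (n - 1)];
  gamma[3 * (n - 1) + 1] = alpha[3 * (n - 1) + 1];
  gamma[3 * (n - 1) + 2] = alpha[3 * (n - 1) + 2];
  double M[9];
  for (int j = n - 1; j >= 1; --j) {
    row_M(phi[j], psi[j], eta[j], lam[j], pdet[j], ao[j], ev[j], dv[j], M);
    // states forbidden at year j contribute nothing backwards
    double cP = bP, cA = bA, cD = bD;
    apply_mask(mask[j], cP, cA, cD);
    double pP = M[0] * cP + M[1] * cA + M[2] * cD;
    double pA = M[3] * cP + M[4] * cA + M[5] * cD;
    double pD = M[8] * cD;
    const double s = pP + pA + pD;
    if (s > 0.0) { pP /= s; pA /= s; pD /= s; }
    double gP = alpha[3 * (j - 1)] * pP;
    double gA = alpha[3 * (j - 1) + 1] * pA;
    double gD = alpha[3 * (j - 1) + 2] * pD;
    const double gs = gP + gA + gD;
    if (gs > 0.0) { gP /= gs; gA /= gs; gD /= gs; }
    gamma[3 * (j - 1)] = gP; gamma[3 * (j - 1) + 1] = gA; gamma[3 * (j - 1) + 2] = gD;
    bP = pP; bA = pA; bD = pD;
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_forward(NumericVector phi, NumericVector psi, NumericVector eta,
                 NumericVector lam, NumericVector pdet, IntegerVector anyobs,
                 IntegerVector ev, IntegerVector dv, IntegerVector mask,
                 bool smooth) {
  const int n = phi.size();
  if (!smooth) {
    double ll = forward_one(n, phi.begin(), psi.begin(), eta.begin(), lam.begin(),
                            pdet.begin(), anyobs.begin(), ev.begin(), dv.begin(),
                            mask.begin(), nullptr);
    return List::create(_["loglik"] = ll);
  }
  std::vector<double> alpha(3 * n), gamma(3 * n, NA_REAL);
  double ll = fb_one(n, phi.begin(), psi.begin(), eta.begin(), lam.begin(),
                     pdet.begin(), anyobs.begin(), ev.begin(), dv.begin(),
                     mask.begin(), alpha.data(), gamma.data());
  NumericMatrix g(n, 3);
  for (int j = 0; j < n; ++j)
    for (int s = 0; s < 3; ++s) g(j, s) = gamma[3 * j + s];
  return List::create(_["loglik"] = ll, _["state_posterior"] = g);
}

// Fill per-row probability caches from a coefficient matrix
// (rows: theta_1..theta_L, phi, psi, eta, lambda).
static void fill_all(const arma::mat& X, const arma::mat& beta,
                     const IntegerMatrix& O, int L, std::vector<double>& phi,
                     std::vector<double>& psi, std::vector<double>& eta,
                     std::vector<double>& lam, std::vector<double>& pdet,
                     arma::mat* term) {
  const int n = X.n_rows;
  arma::vec lp(n);
  std::fill(pdet.begin(), pdet.end(), 1.0);
  for (int l = 0; l < L; ++l) {
    lp = X * beta.row(l).t();
    for (int i = 0; i < n; ++i) {
      const double th = inv_logit(lp(i));
      const double t = O(i, l) ? th : 1.0 - th;
      if (term) (*term)(i, l) = t;
      pdet[i] *= t;
    }
  }
  lp = X * beta.row(L).t();     for (int i = 0; i < n; ++i) phi[i] = inv_logit(lp(i));
  lp = X * beta.row(L + 1).t(); for (int i = 0; i < n; ++i) psi[i] = inv_logit(lp(i));
  lp = X * beta.row(L + 2).t(); for (int i = 0; i < n; ++i) eta[i] = inv_logit(lp(i));
  lp = X * beta.row(L + 3).t(); for (int i = 0; i < n; ++i) lam[i] = inv_logit(lp(i));
}

// [[Rcpp::export]]
List cpp_cohort_loglik(const arma::mat& X, const arma::mat& beta,
                       const IntegerMatrix& O, IntegerVector anyobs,
                       IntegerVector ev, IntegerVector dv, IntegerVector mask,
                       IntegerVector ptr) {
  const int n = X.n_rows, L = O.ncol(), I = ptr.size() - 1;
  std::vector<double> phi(n), psi(n), eta(n), lam(n), pdet(n);
  fill_all(X, beta, O, L, phi, psi, eta, lam, pdet, nullptr);
  NumericVector by_ind(I);
  double total = 0.0;
  for (int i = 0; i < I; ++i) {
    const int j0 = ptr[i], len = ptr[i + 1] - ptr[i];
    const double ll = forward_one(len, &phi[j0], &psi[j0], &eta[j0], &lam[j0],
                                  &pdet[j0], &anyobs[j0], &ev[j0], &dv[j0],
                                  &mask[j0], nullptr);
    by_ind[i] = ll;
    total += ll;
  }
  return List::create(_["total"] = total, _["by_individual"] = by_ind);
}

// Blocked adaptive random-walk Metropolis on the marginalized posterior.
// Blocks: one per linear predictor (theta_1..theta_L, phi, psi, eta, lambda).
// During burn-in each block adapts a scalar step size towards `target`
// acceptance and an empirical proposal covariance (Haario-style); both are
// frozen afterwards so the post-burn-in chain satisfies detailed balance.
// [[Rcpp::export]]
List cpp_mcmc(const arma::mat& X, const IntegerMatrix& O, IntegerVector anyobs,
              IntegerVector ev, IntegerVector dv, IntegerVector mask,
              IntegerVector ptr, const arma::mat& beta_init, double delta,
              int n_iter, int burnin, int thin, bool use_lik, double target,
              int n_sweeps) {
  const int n = X.n_rows, L = O.ncol(), I = ptr.size() - 1;
  const int B = beta_init.n_rows, p = beta_init.n_cols, K = B * p;
  arma::mat beta = beta_init;

  std::vector<double> phi(n), psi(n), eta(n), lam(n), pdet(n);
  std::vector<double> scr(n), pdet_s(n);
  arma::mat term(n, L);
  fill_all(X, beta, O, L, phi, psi, eta, lam, pdet, &term);

  auto total_ll = [&](const double* f, const double* s, const double* h,
                      const double* l, const double* pd) -> double {
    if (!use_lik) return 0.0;
    double tot = 0.0;
    for (int i = 0; i < I; ++i) {
      const int j0 = ptr[i], len = ptr[i + 1] - ptr[i];
      const double ll = forward_one(len, f + j0, s + j0, h + j0, l + j0,
                                    pd + j0, &anyobs[j0], &ev[j0], &dv[j0],
                                    &mask[j0], nullptr);
      if (!R_FINITE(ll)) return R_NegInf;
      tot += ll;
    }
    return tot;
  };

  double ll_cur = total_ll(phi.data(), psi.data(), eta.data(), lam.data(), pdet.data());
  if (!R_FINITE(ll_cur))
    stop("log-posterior is not finite at initialization; check the data for inconsistencies or re-initialize");

  arma::vec lp(n);
  // adaptation state per block: proposals start preconditioned by the
  // design-based covariance (X'X/n)^{-1}, the natural metric for a
  // logistic-link predictor, with the overall scale adapted to the target
  // acceptance rate during burn-in.
  arma::mat C0 = arma::eye<arma::mat>(p, p);
  if (use_lik) {
    arma::mat info = X.t() * X / std::max(n, 1) + 1e-6 * arma::eye<arma::mat>(p, p);
    arma::mat Ci;
    if (arma::inv_sympd(Ci, info)) {
      arma::mat Lc;
      if (arma::chol(Lc, Ci + 1e-8 * arma::eye<arma::mat>(p, p), "lower")) C0 = Lc;
    }
  }
  std::vector<arma::mat> cholL(B, C0);
  arma::vec lscale(B);
  lscale.fill(std::log(2.38 / std::sqrt((double)p * std::max(n, 1))));
  if (!use_lik) lscale.fill(std::log(2.38 / std::sqrt((double)p)));
  std::vector<arma::vec> mu(B, arma::zeros<arma::vec>(p));
  std::vector<arma::mat> M2(B, arma::zeros<arma::mat>(p, p));
  arma::ivec cnt(B, arma::fill::zeros);
  arma::vec acc_post(B, arma::fill::zeros), prop_post(B, arma::fill::zeros);

  const int n_kept = (n_iter - burnin) / thin;
  arma::mat draws(std::max(n_kept, 0), K);
  NumericVector ll_kept(std::max(n_kept, 0));
  int kept = 0;

  arma::vec z(p), step(p);
  for (int it = 1; it <= n_iter; ++it) {
    for (int sw = 0; sw < n_sweeps; ++sw)
    for (int b = 0; b < B; ++b) {
      for (int j = 0; j < p; ++j) z(j) = norm_rand();
      step = std::exp(lscale(b)) * (cholL[b] * z);
      arma::rowvec cur = beta.row(b);
      arma::rowvec prop = cur + step.t();

      double ll_new;
      if (b < L) {
        lp = X * prop.t();
        for (int i = 0; i < n; ++i) {
          const double th = inv_logit(lp(i));
          scr[i] = O(i, b) ? th : 1.0 - th;
        }
        for (int i = 0; i < n; ++i) {
          double v = 1.0;
          for (int l = 0; l < L; ++l) v *= (l == b) ? scr[i] : term(i, l);
          pdet_s[i] = v;
        }
        ll_new = total_ll(phi.data(), psi.data(), eta.data(), lam.data(), pdet_s.data());
      } else {
        lp = X * prop.t();
        for (int i = 0; i < n; ++i) scr[i] = inv_logit(lp(i));
        const double* f = (b == L)     ? scr.data() : phi.data();
        const double* s = (b == L + 1) ? scr.data() : psi.data();
        const double* h = (b == L + 2) ? scr.data() : eta.data();
        const double* l = (b == L + 3) ? scr.data() : lam.data();
        ll_new = total_ll(f, s, h, l, pdet.data());
      }

      const double logr = ll_new - ll_cur -
        0.5 / delta * (arma::dot(prop, prop) - arma::dot(cur, cur));
      const double a = R_FINITE(ll_new) ? std::min(1.0, std::exp(std::min(logr, 0.0))) : 0.0;
      const bool accept = R_FINITE(ll_new) && std::log(unif_rand()) < logr;
      if (accept) {
        beta.row(b) = prop;
        ll_cur = ll_new;
        if (b < L) {
          for (int i = 0; i < n; ++i) { term(i, b) = scr[i]; pdet[i] = pdet_s[i]; }
        } else if (b == L)     std::copy(scr.begin(), scr.end(), phi.begin());
        else if (b == L + 1)   std::copy(scr.begin(), scr.end(), psi.begin());
        else if (b == L + 2)   std::copy(scr.begin(), scr.end(), eta.begin());
        else                   std::copy(scr.begin(), scr.end(), lam.begin());
      }

      if (it <= burnin) {
        lscale(b) += std::pow((double)it, -0.6) * (a - target);
        // Welford update of the block's empirical covariance
        cnt(b) += 1;
        arma::vec x = beta.row(b).t();
        arma::vec dlt = x - mu[b];
        mu[b] += dlt / cnt(b);
        M2[b] += dlt * (x - mu[b]).t();
        if (cnt(b) >= std::max(50, 2 * p) && it % 50 == 0) {
          arma::mat C = M2[b] / (cnt(b) - 1.0) + 1e-8 * arma::eye<arma::mat>(p, p);
          arma::mat Lc;
          if (arma::chol(Lc, C, "lower")) cholL[b] = Lc;
        }
      } else {
        prop_post(b) += 1.0;
        if (accept) acc_post(b) += 1.0;
      }
    }
    if (it > burnin && (it - burnin) % thin == 0) {
      for (int b = 0; b < B; ++b)
        for (int j = 0; j < p; ++j) draws(kept, b * p + j) = beta(b, j);
      ll_kept[kept] = ll_cur;
      ++kept;
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }

  arma::vec acc_rate(B);
  for (int b = 0; b < B; ++b)
    acc_rate(b) = prop_post(b) > 0 ? acc_post(b) / prop_post(b) : NA_REAL;
  return List::create(_["draws"] = draws, _["accept_rate"] = acc_rate,
                      _["step_scale"] = arma::exp(lscale), _["loglik"] = ll_kept,
                      _["n_kept"] = kept);
}

// Smoothed presence probabilities over posterior draws.
// Returns the per-row mean of P(present | record, beta) across draws, and,
// for rows assigned to a cell (cell >= 0, e.g. year x subgroup membership in
// the registered set), the per-draw sums of smoothed presence per cell.
// [[Rcpp::export]]
List cpp_presence(const arma::mat& X, const IntegerMatrix& O, IntegerVector anyobs,
                  IntegerVector ev, IntegerVector dv, IntegerVector mask,
                  IntegerVector ptr, const arma::mat& draws, IntegerVector cell,
                  int ncell) {
  const int n = X.n_rows, L = O.ncol(), I = ptr.size() - 1;
  const int M = draws.n_rows;
  const int B = L + 4, p = draws.n_cols / B;
  std::vector<double> phi(n), psi(n), eta(n), lam(n), pdet(n);
  int maxlen = 0;
  for (int i = 0; i < I; ++i) maxlen = std::max(maxlen, ptr[i + 1] - ptr[i]);
  std::vector<double> alpha(3 * maxlen), gamma(3 * maxlen);
  arma::vec zbar(n, arma::fill::zeros);
  arma::mat cellsum(M, std::max(ncell, 1), arma::fill::zeros);
  arma::mat cellvar(M, std::max(ncell, 1), arma::fill::zeros);
  arma::mat beta(B, p);
  for (int m = 0; m < M; ++m) {
    for (int b = 0; b < B; ++b)
      for (int j = 0; j < p; ++j) beta(b, j) = draws(m, b * p + j);
    fill_all(X, beta, O, L, phi, psi, eta, lam, pdet, nullptr);
    for (int i = 0; i < I; ++i) {
      const int j0 = ptr[i], len = ptr[i + 1] - ptr[i];
      const double ll = fb_one(len, &phi[j0], &psi[j0], &eta[j0], &lam[j0],
                               &pdet[j0], &anyobs[j0], &ev[j0], &dv[j0],
                               &mask[j0], alpha.data(), gamma.data());
      if (!R_FINITE(ll))
        stop("record for individual index %d has zero likelihood under a posterior draw", i + 1);
      for (int j = 0; j < len; ++j) {
        const double gP = gamma[3 * j];
        zbar(j0 + j) += gP;
        const int c = cell[j0 + j];
        if (c >= 0) {
          cellsum(m, c) += gP;
          cellvar(m, c) += gP * (1.0 - gP);  // conditional Bernoulli variance
        }
      }
    }
    if (m % 20 == 0) Rcpp::checkUserInterrupt();
  }
  zbar /= (double)M;
  return List::create(_["zhat"] = zbar, _["cell_draws"] = cellsum,
                      _["cell_vars"] = cellvar);
}
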