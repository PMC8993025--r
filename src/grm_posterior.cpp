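#include <Rcpp.h>
using namespace Rcpp;

// Stable logistic function.
static inline double logistic(double z) {
  if (z > 0.0) {
    double e = std::exp(-z);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

// Unconstrained parameter layout (length = sum_i J_i + 3 + P):
//   for each item i with J_i categories:
//     log(lambda_i), tau_{i,2}, log(delta_{i,3}), ..., log(delta_{i,J_i})
//   mu_tau, log(sigma_tau), log(sigma)
//   theta_1, ..., theta_P
//
// The log posterior includes the Jacobian of the log/increment transforms so
// that HMC targets the correct density on the unconstrained space.
// X is persons x items with NA_INTEGER for missing; codes are 1..J_i.

// [[Rcpp::export]]
List grm_lp_grad(NumericVector par, IntegerMatrix X, IntegerVector ncat,
                 double s_lambda, double s_mu, double s_tsd, double s_sigma,
                 double floor_p) {
  const int P = X.nrow();
  const int I = X.ncol();
  int Jmax = 0, npar_items = 0;
  for (int i = 0; i < I; ++i) {
    if (ncat[i] > Jmax) Jmax = ncat[i];
    npar_items += ncat[i];  // 1 slope + (J-1) threshold params
  }
  const int idx_mu = npar_items;
  const int idx_lst = npar_items + 1;
  const int idx_lsig = npar_items + 2;
  const int idx_theta = npar_items + 3;

  std::vector<double> lambda(I), loglam(I);
  std::vector< std::vector<double> > tau(I);
  std::vector<int> offset(I);
  {
    int off = 0;
    for (int i = 0; i < I; ++i) {
      offset[i] = off;
      const int J = ncat[i];
      loglam[i] = par[off];
      lambda[i] = std::exp(par[off]);
      tau[i].resize(J - 1);
      tau[i][0] = par[off + 1];
      for (int j = 1; j < J - 1; ++j)
        tau[i][j] = tau[i][j - 1] + std::exp(par[off + 1 + j]);
      off += J;
    }
  }
  double log_jac_incr = 0.0;  // Jacobian of the log-increment transform
  {
    int off = 0;
    for (int i = 0; i < I; ++i) {
      const int J = ncat[i];
      for (int j = 1; j < J - 1; ++j) log_jac_incr += par[off + 1 + j];
      off += J;
    }
  }
  const double mu_tau = par[idx_mu];
  const double lst = par[idx_lst];
  const double sig_tau = std::exp(lst);
  const double lsig = par[idx_lsig];
  const double sigma = std::exp(lsig);

  double lp = log_jac_incr;
  NumericVector grad(par.size());
  std::vector< std::vector<double> > gtau(I);
  for (int i = 0; i < I; ++i) gtau[i].assign(ncat[i] - 1, 0.0);
  std::vector<double> glam(I, 0.0);
  double gmu = 0.0, gst = 0.0, gsig = 0.0;

  // ---- likelihood ----
  for (int i = 0; i < I; ++i) {
    const int J = ncat[i];
    const double lam = lambda[i];
    const std::vector<double>& tv = tau[i];
    for (int p = 0; p < P; ++p) {
      const int x = X(p, i);
      if (x == NA_INTEGER) continue;
      const double th = par[idx_theta + p];
      double Flo = 1.0, flo = 0.0, Fhi = 0.0, fhi = 0.0;
      if (x > 1) {
        Flo = logistic(lam * (th - tv[x - 2]));
        flo = Flo * (1.0 - Flo);
      }
      if (x < J) {
        Fhi = logistic(lam * (th - tv[x - 1]));
        fhi = Fhi * (1.0 - Fhi);
      }
      double prob = Flo - Fhi;
      if (prob < floor_p) prob = floor_p;
      lp += std::log(prob);
      const double invP = 1.0 / prob;
      grad[idx_theta + p] += lam * (flo - fhi) * invP;
      double gl = 0.0;
      if (x > 1) gl += (th - tv[x - 2]) * flo;
      if (x < J) gl -= (th - tv[x - 1]) * fhi;
      glam[i] += gl * invP;
      if (x > 1) gtau[i][x - 2] -= lam * flo * invP;
      if (x < J) gtau[i][x - 1] += lam * fhi * invP;
    }
  }

  const double half_l2pi = 0.5 * std::log(2.0 * M_PI);

  // ---- priors ----
  for (int i = 0; i < I; ++i) {
    const int J = ncat[i];
    const double lam = lambda[i];
    // half-Cauchy(0, s_lambda) on lambda, plus log-Jacobian of lambda=exp(a)
    lp += M_LN2 - std::log(M_PI * s_lambda) -
          std::log1p((lam / s_lambda) * (lam / s_lambda)) + loglam[i];
    glam[i] += -2.0 * lam / (s_lambda * s_lambda + lam * lam);
    // ordered thresholds, elementwise normal(mu_tau, sigma_tau)
    for (int j = 0; j < J - 1; ++j) {
      const double z = (tau[i][j] - mu_tau) / sig_tau;
      lp += -0.5 * z * z - lst - half_l2pi;
      gtau[i][j] += -z / sig_tau;
      gmu += z / sig_tau;
      gst += (z * z - 1.0) / sig_tau;
    }
  }
  // mu_tau ~ normal(0, s_mu)
  lp += -0.5 * (mu_tau / s_mu) * (mu_tau / s_mu) - std::log(s_mu) - half_l2pi;
  gmu += -mu_tau / (s_mu * s_mu);
  // sigma_tau ~ half-Cauchy(0, s_tsd), Jacobian of exp
  lp += M_LN2 - std::log(M_PI * s_tsd) -
        std::log1p((sig_tau / s_tsd) * (sig_tau / s_tsd)) + lst;
  gst += -2.0 * sig_tau / (s_tsd * s_tsd + sig_tau * sig_tau);
  // theta_p ~ normal(0, sigma)
  for (int p = 0; p < P; ++p) {
    const double th = par[idx_theta + p];
    lp += -0.5 * (th / sigma) * (th / sigma) - lsig - half_l2pi;
    grad[idx_theta + p] += -th / (sigma * sigma);
    gsig += th * th / (sigma * sigma * sigma) - 1.0 / sigma;
  }
  // sigma ~ half-Cauchy(0, s_sigma), Jacobian of exp
  lp += M_LN2 - std::log(M_PI * s_sigma) -
        std::log1p((sigma / s_sigma) * (sigma / s_sigma)) + lsig;
  gsig += -2.0 * sigma / (s_sigma * s_sigma + sigma * sigma);

  // ---- chain rule to unconstrained coordinates ----
  for (int i = 0; i < I; ++i) {
    const int J = ncat[i];
    const int off = offset[i];
    grad[off] = glam[i] * lambda[i] + 1.0;  // +1 from the Jacobian term
    // free first threshold gets the sum of all tau gradients
    double acc = 0.0;
    for (int j = 0; j < J - 1; ++j) acc += gtau[i][j];
    grad[off + 1] = acc;
    // increments: delta_j * (sum of gradients of tau_{>=j}) + 1 (Jacobian)
    for (int j = 1; j < J - 1; ++j) {
      double tail = 0.0;
      for (int k = j; k < J - 1; ++k) tail += gtau[i][k];
      grad[off + 1 + j] = tail * std::exp(par[off + 1 + j]) + 1.0;
    }
  }
  grad[idx_mu] = gmu;
  grad[idx_lst] = gst * sig_tau + 1.0;
  grad[idx_lsig] = gsig * sigma + 1.0;

  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// Total GRM log-likelihood of every person at every quadrature node.
// Returns a P x Q matrix; used by the EM E-step and batch EAP scoring.
// [[Rcpp::export]]
NumericMatrix grm_loglik_nodes(IntegerMatrix X, IntegerVector ncat,
                               NumericVector lambda, List tau_list,
                               NumericVector nodes, double floor_p) {
  const int P = X.nrow();
  const int I = X.ncol();
  const int Q = nodes.size();
  NumericMatrix L(P, Q);
  for (int i = 0; i < I; ++i) {
    const int J = ncat[i];
    const double lam = lambda[i];
    NumericVector tv = tau_list[i];
    // per-node log category probabilities for this item
    std::vector<double> logp(Q * J);
    for (int q = 0; q < Q; ++q) {
      double Fprev = 1.0;
      for (int j = 0; j < J; ++j) {
        double Fnext = (j == J - 1) ? 0.0 : logistic(lam * (nodes[q] - tv[j]));
        double prob = Fprev - Fnext;
        if (prob < floor_p) prob = floor_p;
        logp[q * J + j] = std::log(prob);
        Fprev = Fnext;
      }
    }
    for (int p = 0; p < P; ++p) {
      const int x = X(p, i);
      if (x == NA_INTEGER) continue;
      for (int q = 0; q < Q; ++q) L(p, q) += logp[q * J + (x - 1)];
    }
  }
  return L;
}
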