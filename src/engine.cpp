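// Sequential-fixation (origin-fixation) engine for the coevolution of
// log transcription rates (ln alpha) and log translation rates (ln beta)
// under selection on steady-state log protein levels.
//
// The interaction matrix C is constant through evolution (mutations only
// perturb ln alpha / ln beta), so the 2n x 2n log-linear steady-state
// system has a fixed coefficient matrix: it is inverted once per lineage
// and each proposal costs one matrix-vector product.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double RCOND_TOL = 1e-12;

// Kimura fixation probability, continuous at s = 0 (limit 1/(2Ne)),
// computed with expm1 so strongly deleterious mutations underflow to 0
// instead of overflowing.
double fix_prob(double s, double Ne) {
  double x = 4.0 * Ne * s;
  if (std::fabs(x) < 1e-8) return 1.0 / (2.0 * Ne);
  double num = -std::expm1(-2.0 * s);  // 1 - exp(-2s)
  double den = -std::expm1(-x);        // 1 - exp(-4 Ne s)
  double pf = num / den;
  if (!std::isfinite(pf) || pf < 0.0) pf = 0.0;
  if (pf > 1.0) pf = 1.0;
  return pf;
}

// [[Rcpp::export]]
double fixation_probability_cpp(double s, double Ne) {
  return fix_prob(s, Ne);
}

// Coefficient matrix of the log-linear equilibrium system. Rows come in
// pairs per gene i: the mRNA balance (-lnR_i + sum_j C[j,i] lnP_j =
// ln gammaR - ln alpha_i) and the protein balance (lnR_i - lnP_i =
// ln gammaP - ln beta_i). Unknown order: lnR_1, lnP_1, ..., lnR_n, lnP_n.
static arma::mat network_matrix(const arma::mat& C) {
  int n = C.n_rows;
  arma::mat M(2 * n, 2 * n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    M(2 * i, 2 * i) = -1.0;
    for (int j = 0; j < n; ++j)
      if (j != i) M(2 * i, 2 * j + 1) = C(j, i);
    M(2 * i + 1, 2 * i) = 1.0;
    M(2 * i + 1, 2 * i + 1) = -1.0;
  }
  return M;
}

// [[Rcpp::export]]
List solve_network_cpp(NumericVector ln_alpha, NumericVector ln_beta,
                       NumericVector ln_gamma_R, NumericVector ln_gamma_P,
                       NumericMatrix C) {
  int n = ln_alpha.size();
  arma::mat Cm(C.begin(), n, n, false);
  arma::mat M = network_matrix(Cm);
  double rc = arma::rcond(M);
  if (!std::isfinite(rc) || rc < RCOND_TOL)
    return List::create(_["singular"] = true, _["rcond"] = rc);
  arma::vec rhs(2 * n);
  for (int i = 0; i < n; ++i) {
    rhs(2 * i) = ln_gamma_R[i] - ln_alpha[i];
    rhs(2 * i + 1) = ln_gamma_P[i] - ln_beta[i];
  }
  arma::vec x = arma::solve(M, rhs, arma::solve_opts::no_approx);
  NumericVector lnR(n), lnP(n);
  for (int i = 0; i < n; ++i) {
    lnR[i] = x(2 * i);
    lnP[i] = x(2 * i + 1);
  }
  return List::create(_["singular"] = false, _["rcond"] = rc,
                      _["ln_R"] = lnR, _["ln_P"] = lnP);
}

struct Phenotype {
  arma::vec lnR, lnP;
};

// regime codes: 0 neutral, 1 gaussian (stabilizing/directional),
// 2 functionally-equivalent pair (selection on summed protein)
// [[Rcpp::export]]
List evolve_lineage_cpp(int T, double Ne,
                        NumericVector U_alpha, NumericVector U_beta,
                        NumericVector sigma_alpha, NumericVector sigma_beta,
                        NumericMatrix C,
                        NumericVector ln_gamma_R, NumericVector ln_gamma_P,
                        LogicalVector has_opt, NumericVector ln_opt,
                        NumericVector sigma_omega,
                        int regime, double eq_ln_opt, double eq_sigma_omega,
                        NumericVector init_ln_alpha, NumericVector init_ln_beta,
                        int record_every) {
  int n = U_alpha.size();
  arma::mat Cm(C.begin(), n, n, false);
  bool coupled = arma::any(arma::vectorise(Cm - arma::diagmat(Cm.diag())) != 0.0);

  arma::mat Minv;
  if (coupled) {
    arma::mat M = network_matrix(Cm);
    double rc = arma::rcond(M);
    if (!std::isfinite(rc) || rc < RCOND_TOL)
      stop("no equilibrium: singular interaction system at the starting genotype");
    Minv = arma::inv(M);
  }

  arma::vec la(n), lb(n), lgR(n), lgP(n);
  for (int i = 0; i < n; ++i) {
    la(i) = init_ln_alpha[i];
    lb(i) = init_ln_beta[i];
    lgR(i) = ln_gamma_R[i];
    lgP(i) = ln_gamma_P[i];
  }

  // mutation channel table: channels 0..n-1 hit ln alpha, n..2n-1 ln beta
  std::vector<double> cum(2 * n);
  double sumU = 0.0;
  for (int i = 0; i < n; ++i) sumU += U_alpha[i];
  for (int i = 0; i < n; ++i) sumU += U_beta[i];
  double acc = 0.0;
  for (int i = 0; i < n; ++i) { acc += U_alpha[i] / sumU; cum[i] = acc; }
  for (int i = 0; i < n; ++i) { acc += U_beta[i] / sumU; cum[n + i] = acc; }
  cum[2 * n - 1] = 1.0;
  double lambda = 2.0 * Ne * sumU;

  // phenotype from genotype; returns false when no equilibrium exists
  auto phenotype = [&](const arma::vec& a, const arma::vec& b,
                       Phenotype& ph) -> bool {
    if (!coupled) {
      ph.lnR = a - lgR;
      ph.lnP = a + b - lgR - lgP;
      return true;
    }
    arma::vec rhs(2 * n);
    for (int i = 0; i < n; ++i) {
      rhs(2 * i) = lgR(i) - a(i);
      rhs(2 * i + 1) = lgP(i) - b(i);
    }
    arma::vec x = Minv * rhs;
    if (!x.is_finite()) return false;
    ph.lnR.set_size(n);
    ph.lnP.set_size(n);
    for (int i = 0; i < n; ++i) {
      ph.lnR(i) = x(2 * i);
      ph.lnP(i) = x(2 * i + 1);
    }
    return true;
  };

  auto fitness = [&](const Phenotype& ph) -> double {
    if (regime == 2) {
      double Psum = std::exp(ph.lnP(0)) + std::exp(ph.lnP(1));
      double d = std::log(Psum) - eq_ln_opt;
      return std::exp(-d * d / (2.0 * eq_sigma_omega * eq_sigma_omega));
    }
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      if (has_opt[i]) {
        double d = ph.lnP(i) - ln_opt[i];
        ss += d * d / (2.0 * sigma_omega[i] * sigma_omega[i]);
      }
    }
    return std::exp(-ss);
  };

  Phenotype cur;
  if (!phenotype(la, lb, cur))
    stop("no equilibrium: singular interaction system at the starting genotype");
  double wA = (regime == 0) ? 1.0 : fitness(cur);
  double pf_neutral = 1.0 / (2.0 * Ne);

  // record at t = 0, every record_every steps, and always at t = T
  std::vector<int> rec_times;
  rec_times.push_back(0);
  if (record_every > 0)
    for (int t = record_every; t < T; t += record_every) rec_times.push_back(t);
  rec_times.push_back(T);
  int n_rec = rec_times.size();
  arma::mat rec_la(n_rec, n), rec_lb(n_rec, n), rec_lnR(n_rec, n), rec_lnP(n_rec, n);
  int ri = 0;
  auto record = [&]() {
    rec_la.row(ri) = la.t();
    rec_lb.row(ri) = lb.t();
    rec_lnR.row(ri) = cur.lnR.t();
    rec_lnP.row(ri) = cur.lnP.t();
    ++ri;
  };
  record();

  long n_proposed = 0;
  IntegerVector n_fixed_alpha(n), n_fixed_beta(n);
  Phenotype prop;
  arma::vec la_new = la, lb_new = lb;

  RNGScope scope;
  for (int t = 1; t <= T; ++t) {
    int m = R::rpois(lambda);
    for (int k = 0; k < m; ++k) {
      ++n_proposed;
      double u = unif_rand();
      int ch = 0;
      while (u > cum[ch]) ++ch;
      bool is_alpha = ch < n;
      int gene = is_alpha ? ch : ch - n;
      double eff = norm_rand() *
        (is_alpha ? sigma_alpha[gene] : sigma_beta[gene]);
      la_new = la;
      lb_new = lb;
      if (is_alpha) la_new(gene) += eff; else lb_new(gene) += eff;

      double pf;
      bool ok = phenotype(la_new, lb_new, prop);
      if (regime == 0) {
        pf = pf_neutral;
      } else if (!ok) {
        pf = 0.0;  // no equilibrium -> fitness 0 -> s = -1
      } else {
        double w = fitness(prop);
        double s = w / wA - 1.0;
        pf = fix_prob(s, Ne);
      }
      if (pf > 0.0 && unif_rand() < pf) {
        la = la_new;
        lb = lb_new;
        if (ok) cur = prop;
        if (regime != 0) wA = fitness(cur);
        if (is_alpha) n_fixed_alpha[gene] += 1; else n_fixed_beta[gene] += 1;
      }
    }
    if (ri < n_rec && t == rec_times[ri]) record();
  }

  return List::create(
    _["times"] = IntegerVector(rec_times.begin(), rec_times.end()),
    _["ln_alpha"] = wrap(rec_la), _["ln_beta"] = wrap(rec_lb),
    _["ln_R"] = wrap(rec_lnR), _["ln_P"] = wrap(rec_lnP),
    _["n_proposed"] = (double)n_proposed,
    _["n_fixed_alpha"] = n_fixed_alpha,
    _["n_fixed_beta"] = n_fixed_beta);
}
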