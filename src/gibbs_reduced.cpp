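// Gibbs sampler core for the reduced (two-generation) animal model.
//
// Model (records i = 1..n; strictly two generations; unrelated, non-inbred
// founders; every phenotyped individual a terminal offspring with one
// record):
//   y_i = x_i' b + (a_{s(i)} + a_{d(i)})/2 + m_i + u_{dam(i)} + e_i
// founder breeding values a ~ N(0, s2a I), Mendelian deviations
// m_i ~ N(0, s2a/2), maternal effects u ~ N(0, s2m I), residual
// e ~ N(0, s2e I).
//
// The Mendelian deviations are marginalized analytically: records are then
// conditionally independent with variance v = s2a/2 + s2e, the joint
// location block (b, a, u) is only p + n_founders + n_dams dimensional, and
// the strong coupling between a high-dimensional latent block and s2a that
// cripples mixing in the naive sampler disappears. s2a and s2e lose
// conjugacy (each appears in v) and are updated by univariate slice
// sampling on the log scale; s2m stays conjugate. The posterior is exactly
// that of the usual animal model with scaled inverse-chi-square (V, nu)
// variance priors and N(0, 1e8) fixed-effect priors.
//
// All RNG goes through R's generator, so set.seed() in R gives
// bit-reproducible chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log full conditional of s2e given s2a (and vice versa share this form):
// founders-part handled separately in logpost_a.
static inline double logpost_e(double s2e, double s2a, double SSe, int n,
                               double Ve, double nu_e) {
  if (s2e <= 0.0) return -INFINITY;
  const double v = 0.5 * s2a + s2e;
  return -0.5 * n * std::log(v) - 0.5 * SSe / v
         - (0.5 * nu_e + 1.0) * std::log(s2e) - 0.5 * nu_e * Ve / s2e;
}

static inline double logpost_a(double s2a, double s2e, double SSa, int n_f,
                               double SSe, int n, double Va, double nu_a) {
  if (s2a <= 0.0) return -INFINITY;
  const double v = 0.5 * s2a + s2e;
  return -0.5 * n_f * std::log(s2a) - 0.5 * SSa / s2a
         - (0.5 * nu_a + 1.0) * std::log(s2a) - 0.5 * nu_a * Va / s2a
         - 0.5 * n * std::log(v) - 0.5 * SSe / v;
}

// univariate slice sampler on x = log(sigma2), stepping-out + shrinkage
template <typename LogF>
static double slice_log_scale(double x0, LogF logf, double w = 1.0,
                              int m_max = 50) {
  const double fx0 = logf(x0) + std::log(x0);  // include Jacobian
  const double logy = fx0 - R::exp_rand();     // log of vertical level
  double lx = std::log(x0);
  double L = lx - w * R::unif_rand();
  double Rr = L + w;
  int j = (int)std::floor(m_max * R::unif_rand());
  int k = m_max - 1 - j;
  while (j-- > 0 && logf(std::exp(L)) + L > logy) L -= w;
  while (k-- > 0 && logf(std::exp(Rr)) + Rr > logy) Rr += w;
  for (int it = 0; it < 200; ++it) {
    const double x1 = L + (Rr - L) * R::unif_rand();
    if (logf(std::exp(x1)) + x1 > logy) return std::exp(x1);
    if (x1 < lx) L = x1; else Rr = x1;
  }
  return x0;  // extremely narrow slice; keep current value
}

// [[Rcpp::export]]
List gibbs_reduced_cpp(const arma::vec& y,
                       const arma::mat& W,          // [X | Z_f(1/2) | Z_dam]
                       const arma::uvec& founder_cols,
                       const arma::uvec& dam_cols,
                       int p_fixed,
                       double Va, double nu_a,
                       double Vm, double nu_m,
                       double Ve, double nu_e,
                       int n_iter, int burn_in, int thin) {
  const int n = y.n_elem;
  const int q = W.n_cols;
  const int n_f = founder_cols.n_elem;
  const int n_d = dam_cols.n_elem;
  const bool maternal = n_d > 0;

  arma::mat WtW = W.t() * W;
  arma::vec Wty = W.t() * y;

  double s2a = Va, s2m = maternal ? Vm : 1e-10, s2e = Ve;
  arma::vec g(q, arma::fill::zeros);

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat draws(n_keep, p_fixed + 3);
  arma::vec g_mean(q, arma::fill::zeros);
  const double tiny = 1e-10;
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // --- joint draw of (b, a, u) | variances (Mendelian marginalized) ----
    const double v = 0.5 * s2a + s2e;
    arma::mat C = WtW / v;
    for (int j = 0; j < p_fixed; ++j) C(j, j) += 1e-8;
    for (arma::uword k = 0; k < founder_cols.n_elem; ++k)
      C(founder_cols(k), founder_cols(k)) += 1.0 / s2a;
    for (arma::uword k = 0; k < dam_cols.n_elem; ++k)
      C(dam_cols(k), dam_cols(k)) += 1.0 / s2m;
    arma::mat L;
    if (!arma::chol(L, C, "lower")) {
      C.diag() += 1e-8 * arma::max(C.diag());
      if (!arma::chol(L, C, "lower"))
        stop("mixed-model equations not positive definite");
    }
    arma::vec rhs = Wty / v;
    arma::vec w1 = arma::solve(arma::trimatl(L), rhs);
    arma::vec mu_g = arma::solve(arma::trimatu(L.t()), w1);
    arma::vec z(q);
    for (int j = 0; j < q; ++j) z(j) = R::norm_rand();
    g = mu_g + arma::solve(arma::trimatu(L.t()), z);

    // --- sufficient statistics ------------------------------------------
    arma::vec e = y - W * g;          // Mendelian + residual
    const double SSe = arma::dot(e, e);
    double SSa = 0.0;
    for (arma::uword k = 0; k < founder_cols.n_elem; ++k) {
      const double a = g(founder_cols(k));
      SSa += a * a;
    }

    // --- variance components --------------------------------------------
    s2e = slice_log_scale(s2e, [&](double x) {
      return logpost_e(x, s2a, SSe, n, Ve, nu_e); });
    if (s2e < tiny) s2e = tiny;

    s2a = slice_log_scale(s2a, [&](double x) {
      return logpost_a(x, s2e, SSa, n_f, SSe, n, Va, nu_a); });
    if (s2a < tiny) s2a = tiny;

    if (maternal) {
      double ss_m = 0.0;
      for (arma::uword k = 0; k < dam_cols.n_elem; ++k) {
        const double u = g(dam_cols(k));
        ss_m += u * u;
      }
      s2m = (nu_m * Vm + ss_m) / R::rchisq(nu_m + n_d);
      if (s2m < tiny) s2m = tiny;
    }

    // --- record ----------------------------------------------------------
    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < p_fixed; ++j) draws(kept, j) = g(j);
      draws(kept, p_fixed) = s2a;
      draws(kept, p_fixed + 1) = s2m;
      draws(kept, p_fixed + 2) = s2e;
      g_mean += g;
      ++kept;
    }
  }
  if (kept > 0) g_mean /= kept;

  return List::create(_["draws"] = draws, _["effect_means"] = g_mean);
}
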