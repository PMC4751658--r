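// Data-augmentation Gibbs sampler for the binary probit threshold model
//   Pr(y = 1 | eta) = Phi(eta - delta),  eta = W b + Z u,  delta fixed at 0
// with liability l = eta + e, e ~ N(0, I) (residual variance fixed at 1 for
// identifiability).  Marker-effect priors:
//   0 = ridge      u_j ~ N(0, sigma2_u),             common variance
//   1 = bayes_a    u_j ~ N(0, sigma2_j),             per-feature variances
//   2 = bayes_c_pi u_j ~ pi N(0, sigma2_u) + (1-pi) delta_0, spike-slab
// Variance components carry scaled-inverse-chi-square priors (df_u, scale_u);
// pi ~ Beta(pi_a, pi_b) with inclusion indicators sampled with the effect
// integrated out of the likelihood ratio.
// Uses the R RNG throughout so results are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double CLAMP_SD = 8.0; // truncated-normal draws clamped to mean +/- 8 sd

// inverse-CDF truncated standard-normal liability draw around mean eta,
// truncated below (y=1) or above (y=0) at zero
static inline double draw_liability(double eta, int y) {
  double plo = R::pnorm(0.0, eta, 1.0, 1, 0); // Pr(l < 0)
  double v;
  if (y == 1) {
    v = plo + unif_rand() * (1.0 - plo);
  } else {
    v = unif_rand() * plo;
  }
  if (v < 1e-12) v = 1e-12;
  if (v > 1.0 - 1e-12) v = 1.0 - 1e-12;
  double l = R::qnorm(v, eta, 1.0, 1, 0);
  if (l > eta + CLAMP_SD) l = eta + CLAMP_SD;
  if (l < eta - CLAMP_SD) l = eta - CLAMP_SD;
  return l;
}

// scaled-inverse-chi-square draw: (ss + df*scale) / chisq(df + n)
static inline double draw_scaled_inv_chisq(double ss, double n, double df, double scale) {
  return (ss + df * scale) / R::rchisq(df + n);
}

// Ridge-prior effect updates are done as one joint multivariate-normal block
// draw per iteration (Albert-Chib style), made O(m * r) by a thin SVD of
// Z = U_s diag(sv) V' supplied from R: components along V are drawn with
// variance 1/(sv^2 + lambda), the null-space components i.i.d. with variance
// 1/lambda.  Single-site updates on m correlated marker columns leave the
// overall genetic-variance mode of the chain practically frozen; the block
// draw removes that pathology.  BayesA and BayesC-pi keep single-site
// updates (their per-feature variances/indicators need them).

// [[Rcpp::export]]
List gibbs_probit_cpp(const IntegerVector& y,
                      const arma::mat& W,
                      const arma::mat& Z,
                      int prior,
                      int n_iter, int burn_in, int thin,
                      double df_u, double scale_u,
                      double pi_a, double pi_b,
                      bool save_effects,
                      const arma::mat& Us, const arma::vec& sv,
                      const arma::mat& V) {
  const int n = y.size();
  const int p = W.n_cols;
  const int m = Z.n_cols;

  arma::vec wtw(p), ztz(m);
  for (int j = 0; j < p; ++j) wtw(j) = arma::dot(W.col(j), W.col(j));
  for (int j = 0; j < m; ++j) ztz(j) = arma::dot(Z.col(j), Z.col(j));

  arma::vec b(p, arma::fill::zeros);
  arma::vec u(m, arma::fill::zeros);
  arma::vec l(n), e(n);
  for (int i = 0; i < n; ++i) l(i) = (y[i] == 1) ? 0.5 : -0.5;
  e = l; // eta starts at zero

  double sigma2_u = scale_u;          // ridge / bayes_c_pi common variance
  arma::vec sigma2_j(m);              // bayes_a per-feature variances
  sigma2_j.fill(scale_u);
  double pi = 0.5;
  std::vector<int> incl(m, 1);        // bayes_c_pi inclusion indicators

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat B(n_keep, p), U;
  if (save_effects) U.set_size(n_keep, m);
  arma::vec S2(n_keep), PI(n_keep), NIN(n_keep), VARG(n_keep);
  arma::vec incl_prob(m, arma::fill::zeros);
  arma::vec mean_l(n, arma::fill::zeros), mean_g(n, arma::fill::zeros);
  arma::vec mean_u(m, arma::fill::zeros), mean_b(p, arma::fill::zeros);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // --- liabilities ---
    for (int i = 0; i < n; ++i) {
      double eta = l(i) - e(i);
      double lnew = draw_liability(eta, y[i]);
      e(i) += lnew - l(i);
      l(i) = lnew;
    }

    // --- fixed effects, flat prior ---
    for (int j = 0; j < p; ++j) {
      if (wtw(j) <= 0) continue;
      double rhs = arma::dot(W.col(j), e) + wtw(j) * b(j);
      double bn = rhs / wtw(j) + norm_rand() / std::sqrt(wtw(j));
      e += W.col(j) * (b(j) - bn);
      b(j) = bn;
    }

    // --- feature effects ---
    if (prior == 0) {
      // joint block draw of u | l, b via the thin SVD of Z
      const int r = sv.n_elem;
      arma::vec resid = e + Z * u;         // l - W b
      arma::vec zr = Us.t() * resid;       // r-vector: U_s' (l - W b)
      double lambda = 1.0 / sigma2_u;
      arma::vec a(r);
      for (int k = 0; k < r; ++k) {
        double prec = sv(k) * sv(k) + lambda;
        a(k) = sv(k) * zr(k) / prec + norm_rand() / std::sqrt(prec);
      }
      arma::vec un;
      if ((int)V.n_rows == m && r < m) {
        // null-space components are prior draws with variance 1/lambda
        arma::vec w(m);
        for (int j = 0; j < m; ++j) w(j) = norm_rand();
        arma::vec w_par = V.t() * w;
        un = V * (a - w_par / std::sqrt(lambda)) + w / std::sqrt(lambda);
      } else {
        un = V * a;
      }
      e += Z * (u - un);
      u = un;
      sigma2_u = draw_scaled_inv_chisq(arma::dot(u, u), (double)m, df_u, scale_u);
    } else if (prior == 1) {
      for (int j = 0; j < m; ++j) {
        if (ztz(j) <= 0) { u(j) = 0.0; continue; }
        double C = ztz(j) + 1.0 / sigma2_j(j);
        double rhs = arma::dot(Z.col(j), e) + ztz(j) * u(j);
        double un = rhs / C + norm_rand() / std::sqrt(C);
        e += Z.col(j) * (u(j) - un);
        u(j) = un;
        sigma2_j(j) = draw_scaled_inv_chisq(un * un, 1.0, df_u, scale_u);
      }
    } else {
      // bayes_c_pi: indicator with effect integrated out, then effect
      int n_in = 0;
      double ssu = 0.0;
      double logit_pi = std::log(pi) - std::log1p(-pi);
      for (int j = 0; j < m; ++j) {
        if (ztz(j) <= 0) { u(j) = 0.0; incl[j] = 0; continue; }
        double rhs = arma::dot(Z.col(j), e) + ztz(j) * u(j); // effect removed
        double v1 = ztz(j) * sigma2_u + 1.0;
        double logodds = logit_pi - 0.5 * std::log(v1)
          + 0.5 * rhs * rhs * sigma2_u / v1;
        double p_in = 1.0 / (1.0 + std::exp(-logodds));
        double u_old = u(j);
        if (unif_rand() < p_in) {
          double C = ztz(j) + 1.0 / sigma2_u;
          double un = rhs / C + norm_rand() / std::sqrt(C);
          u(j) = un; incl[j] = 1; ++n_in; ssu += un * un;
        } else {
          u(j) = 0.0; incl[j] = 0;
        }
        if (u(j) != u_old) e += Z.col(j) * (u_old - u(j));
      }
      sigma2_u = draw_scaled_inv_chisq(ssu, (double)n_in, df_u, scale_u);
      pi = R::rbeta(pi_a + n_in, pi_b + (m - n_in));
    }

    // --- record ---
    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      for (int j = 0; j < p; ++j) B(kept, j) = b(j);
      if (save_effects) for (int j = 0; j < m; ++j) U(kept, j) = u(j);
      S2(kept) = (prior == 1) ? arma::mean(sigma2_j) : sigma2_u;
      PI(kept) = pi;
      int nin = 0;
      if (prior == 2) { for (int j = 0; j < m; ++j) { nin += incl[j]; incl_prob(j) += incl[j]; } }
      NIN(kept) = nin;
      arma::vec g = l - e - W * b; // genetic values Z u
      VARG(kept) = arma::var(g, 1); // population variance of Zu this draw
      mean_l += l; mean_g += g; mean_u += u; mean_b += b;
      ++kept;
    }
  }

  incl_prob /= std::max(kept, 1);
  mean_l /= std::max(kept, 1); mean_g /= std::max(kept, 1);
  mean_u /= std::max(kept, 1); mean_b /= std::max(kept, 1);

  List out = List::create(
    _["b"] = B, _["sigma2_u"] = S2, _["pi"] = PI, _["n_included"] = NIN,
    _["var_g"] = VARG, _["incl_prob"] = incl_prob,
    _["post_mean_liability"] = mean_l, _["post_mean_g"] = mean_g,
    _["post_mean_u"] = mean_u, _["post_mean_b"] = mean_b,
    _["n_kept"] = kept);
  if (save_effects) out["u"] = U;
  return out;
}
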