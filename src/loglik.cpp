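// Compiled likelihood cores for the selection model and the
// shared-parameter joint model. Both are evaluated thousands of times per
// fit inside quasi-Newton iterations and numerical Hessians, so the inner
// loops live here; all preparation (grouping, exposure segments,
// quadrature rules, empirical-Bayes centering) happens once in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double relexpm1(double z) {
  // expm1(z)/z with the z -> 0 limit
  if (std::fabs(z) < 1e-8) return 1.0 + 0.5 * z;
  return std::expm1(z) / z;
}

static inline double log1p_exp(double x) {
  // log(1 + exp(x)) without overflow
  if (x > 0) return x + std::log1p(std::exp(-x));
  return std::log1p(std::exp(x));
}

// Selection-model joint log-likelihood over (dropout index, arm) groups.
// Each group g carries: Y (m x d observed scores), tt (times up to
// min(d+1, J)), arm, d; the dropout integral uses Gauss-Hermite nodes on
// the conditional-normal scale.
// [[Rcpp::export]]
double sm_loglik_cpp(List groups, int J,
                     arma::vec beta, arma::mat G, double sigma2,
                     arma::vec psi, arma::vec ghx, arma::vec ghw) {
  const double log2pi = std::log(2.0 * M_PI);
  const double sqpi = std::sqrt(M_PI);
  double ll = 0.0;
  int ngr = groups.size();
  for (int gi = 0; gi < ngr; ++gi) {
    List g = groups[gi];
    arma::mat Y = g["Y"];
    arma::vec tt = g["tt"];
    int d = as<int>(g["d"]);
    double arm = as<double>(g["arm"]);
    int m = Y.n_rows;
    int nt = tt.n_elem;
    arma::mat Z(nt, 2);
    Z.col(0).ones();
    Z.col(1) = tt;
    arma::mat V = Z * G * Z.t();
    V.diag() += sigma2;
    arma::mat R;
    if (!arma::chol(R, V)) return -std::numeric_limits<double>::infinity();
    arma::vec mu = beta(0) + (beta(1) + beta(2) * arm) * tt;
    arma::mat Robs = R.submat(0, 0, d - 1, d - 1);
    arma::mat E = Y.each_row() - mu.subvec(0, d - 1).t();
    arma::mat U = arma::solve(arma::trimatl(Robs.t()), E.t());
    double logdet = 2.0 * arma::accu(arma::log(Robs.diag()));
    ll += -0.5 * m * (d * log2pi + logdet) - 0.5 * arma::accu(U % U);
    // stay-in factors over observed consecutive pairs
    int n_pairs = (d == J) ? (J - 1) : (d - 1);
    for (int i = 0; i < m; ++i) {
      for (int j = 0; j < n_pairs; ++j) {
        double lp = psi(0) + psi(1) * Y(i, j) + psi(2) * Y(i, j + 1);
        ll -= log1p_exp(lp); // log(1 - plogis(lp))
      }
    }
    // dropout factor: marginalize the unobserved next score
    if (d < J) {
      arma::vec r = R.submat(0, d, d - 1, d).col(0);
      arma::vec w = arma::solve(arma::trimatu(Robs), r);
      double csd = R(d, d); // conditional SD of the next score
      arma::vec cmean = mu(d) + E * w;
      double sc = psi(2) * std::sqrt(2.0) * csd;
      int nn = ghx.n_elem;
      for (int i = 0; i < m; ++i) {
        double base = psi(0) + psi(1) * Y(i, d - 1) + psi(2) * cmean(i);
        double s = 0.0;
        for (int k = 0; k < nn; ++k) {
          double lp = base + sc * ghx(k);
          s += ghw(k) / (1.0 + std::exp(-lp));
        }
        s /= sqpi;
        if (s <= 0.0) return -std::numeric_limits<double>::infinity();
        ll += std::log(s);
      }
    }
  }
  return ll;
}

static inline double drelexpm1(double z) {
  // derivative of expm1(z)/z: (z e^z - expm1(z)) / z^2, stable near 0
  if (std::fabs(z) < 1e-4) return 0.5 + z / 3.0 + z * z / 8.0;
  return (z * std::exp(z) - std::expm1(z)) / (z * z);
}

// Shared-parameter model log-likelihood by pseudo-adaptive Gauss-Hermite
// quadrature. Exposure segments come in CSR layout: subject i owns rows
// ex_ptr[i] .. ex_ptr[i+1]-1 of (ex_q, ex_l, ex_u).
// [[Rcpp::export]]
double spm_loglik_cpp(arma::mat st, arma::vec arm, arma::vec Tvec,
                      arma::ivec event, arma::ivec qT,
                      arma::ivec ex_ptr, arma::ivec ex_q,
                      arma::vec ex_l, arma::vec ex_u,
                      arma::mat modes, arma::mat B, arma::vec logdetB,
                      arma::vec ghx1, arma::vec ghx2, arma::vec ghlw,
                      arma::vec xsq,
                      arma::vec beta, arma::mat G, double sigma2,
                      double gamma, double alpha, arma::vec xi) {
  const double log2pi = std::log(2.0 * M_PI);
  const double neg_inf = -std::numeric_limits<double>::infinity();
  int n = st.n_rows;
  int K = ghx1.n_elem;
  double detG = G(0, 0) * G(1, 1) - G(0, 1) * G(1, 0);
  if (detG <= 0.0 || G(0, 0) <= 0.0) return neg_inf;
  double ldG = std::log(detG);
  double gi00 = G(1, 1) / detG, gi11 = G(0, 0) / detG,
         gi01 = -G(0, 1) / detG;
  arma::vec lxi = arma::log(xi);
  double ls2 = std::log(2.0 * M_PI * sigma2);
  const double sq2 = std::sqrt(2.0);
  std::vector<double> buf(K);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = st(i, 0), Sy = st(i, 1), Sty = st(i, 2), Syy = st(i, 3),
           St = st(i, 4), Stt = st(i, 5);
    double gfix = beta(1) + beta(2) * arm(i);
    double Se = Sy - beta(0) * d - gfix * St;
    double Ste = Sty - beta(0) * St - gfix * Stt;
    double See = Syy - 2.0 * beta(0) * Sy - 2.0 * gfix * Sty +
      beta(0) * beta(0) * d + 2.0 * beta(0) * gfix * St + gfix * gfix * Stt;
    double m0 = modes(i, 0), m1 = modes(i, 1);
    double b11 = B(i, 0), b21 = B(i, 1), b22 = B(i, 2);
    double gl = gamma * arm(i);
    double mx = neg_inf;
    for (int k = 0; k < K; ++k) {
      double b0 = m0 + sq2 * b11 * ghx1(k);
      double b1 = m1 + sq2 * (b21 * ghx1(k) + b22 * ghx2(k));
      // longitudinal part from sufficient statistics
      double rss = See - 2.0 * b0 * Se - 2.0 * b1 * Ste +
        b0 * b0 * d + 2.0 * b0 * b1 * St + b1 * b1 * Stt;
      double ll_long = -0.5 * d * ls2 - rss / (2.0 * sigma2);
      // survival part: closed-form cumulative hazard over exposure segments
      double a0 = beta(0) + b0;
      double s = gfix + b1;
      double ch = 0.0;
      for (int r = ex_ptr(i); r < ex_ptr(i + 1); ++r) {
        double dl = ex_u(r) - ex_l(r);
        double z = alpha * s * dl;
        ch += xi(ex_q(r) - 1) * dl *
          std::exp(gl + alpha * (a0 + s * ex_l(r))) * relexpm1(z);
      }
      double ll_surv = -ch;
      if (event(i) == 1) {
        ll_surv += lxi(qT(i) - 1) + gl + alpha * (a0 + s * Tvec(i));
      }
      // random-effects prior
      double qb = gi00 * b0 * b0 + 2.0 * gi01 * b0 * b1 + gi11 * b1 * b1;
      double ll_prior = -log2pi - 0.5 * ldG - 0.5 * qb;
      double v = ghlw(k) + xsq(k) + M_LN2 + logdetB(i) +
        ll_long + ll_surv + ll_prior;
      buf[k] = v;
      if (v > mx) mx = v;
    }
    if (!std::isfinite(mx)) return neg_inf;
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += std::exp(buf[k] - mx);
    ll += mx + std::log(acc);
  }
  return ll;
}

// Joint value and analytic gradient of the SPM log-likelihood in the
// optimizer coordinates: (beta0, beta1, beta2, th1, th2, th3, log sigma2,
// gamma, alpha, log xi_1..Q) where G = L L' with L = [[e^th1, 0],
// [th2, e^th3]]. Node positions are fixed by the pseudo-adaptive
// centering, so no gradient flows through them; per-subject gradients are
// posterior-weighted averages over the quadrature nodes.
// [[Rcpp::export]]
List spm_loglik_grad_cpp(arma::mat st, arma::vec arm, arma::vec Tvec,
                         arma::ivec event, arma::ivec qT,
                         arma::ivec ex_ptr, arma::ivec ex_q,
                         arma::vec ex_l, arma::vec ex_u,
                         arma::mat modes, arma::mat B, arma::vec logdetB,
                         arma::vec ghx1, arma::vec ghx2, arma::vec ghlw,
                         arma::vec xsq,
                         arma::vec beta, arma::vec theta,
                         double gamma, double alpha, arma::vec lxi) {
  const double log2pi = std::log(2.0 * M_PI);
  const double neg_inf = -std::numeric_limits<double>::infinity();
  const double sq2 = std::sqrt(2.0);
  int n = st.n_rows;
  int K = ghx1.n_elem;
  int Q = lxi.n_elem;
  int P = 9 + Q;
  // variance components from the log-Cholesky parameters
  double L11 = std::exp(theta(0)), L21 = theta(1), L22 = std::exp(theta(2));
  arma::mat G(2, 2);
  G(0, 0) = L11 * L11;
  G(0, 1) = G(1, 0) = L11 * L21;
  G(1, 1) = L21 * L21 + L22 * L22;
  double sigma2 = std::exp(theta(3)); // theta(3) = log sigma2 here
  double detG = G(0, 0) * G(1, 1) - G(0, 1) * G(1, 0);
  arma::vec grad(P, arma::fill::zeros);
  if (detG <= 0.0) return List::create(_["value"] = neg_inf,
                                       _["gradient"] = grad);
  double ldG = std::log(detG);
  double gi00 = G(1, 1) / detG, gi11 = G(0, 0) / detG,
         gi01 = -G(0, 1) / detG;
  arma::vec xi = arma::exp(lxi);
  double ls2 = std::log(2.0 * M_PI * sigma2);
  // dG/dtheta_j contracted later with dprior/dG
  double dG1[3] = {2.0 * L11 * L11, L11 * L21, 0.0};       // dG/dth1
  double dG2[3] = {0.0, L11, 2.0 * L21};                    // dG/dth2
  double dG3[3] = {0.0, 0.0, 2.0 * L22 * L22};              // dG/dth3
  std::vector<double> bufL(K), g_scratch(K * P);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = st(i, 0), Sy = st(i, 1), Sty = st(i, 2), Syy = st(i, 3),
           St = st(i, 4), Stt = st(i, 5);
    double gfix = beta(1) + beta(2) * arm(i);
    double Se = Sy - beta(0) * d - gfix * St;
    double Ste = Sty - beta(0) * St - gfix * Stt;
    double See = Syy - 2.0 * beta(0) * Sy - 2.0 * gfix * Sty +
      beta(0) * beta(0) * d + 2.0 * beta(0) * gfix * St + gfix * gfix * Stt;
    double m0 = modes(i, 0), m1 = modes(i, 1);
    double b11 = B(i, 0), b21 = B(i, 1), b22 = B(i, 2);
    double gl = gamma * arm(i);
    int ev = event(i);
    double mx = neg_inf;
    for (int k = 0; k < K; ++k) {
      double *gk = &g_scratch[k * P];
      for (int p = 0; p < P; ++p) gk[p] = 0.0;
      double b0 = m0 + sq2 * b11 * ghx1(k);
      double b1 = m1 + sq2 * (b21 * ghx1(k) + b22 * ghx2(k));
      // longitudinal
      double r1 = Se - b0 * d - b1 * St;     // sum of residuals
      double rt = Ste - b0 * St - b1 * Stt;  // sum of t * residuals
      double rss = See - 2.0 * b0 * Se - 2.0 * b1 * Ste +
        b0 * b0 * d + 2.0 * b0 * b1 * St + b1 * b1 * Stt;
      double ll_long = -0.5 * d * ls2 - rss / (2.0 * sigma2);
      // survival with per-segment derivative accumulators
      double a0 = beta(0) + b0;
      double s = gfix + b1;
      double C0 = std::exp(gl + alpha * a0);
      double El = 1.0; // exp(alpha * s * l) chained over segments
      double ch = 0.0, U = 0.0;
      for (int r = ex_ptr(i); r < ex_ptr(i + 1); ++r) {
        double l = ex_l(r), dl = ex_u(r) - l;
        double z = alpha * s * dl;
        double rz = relexpm1(z);
        double tau = xi(ex_q(r) - 1) * C0 * dl * rz * El;
        ch += tau;
        // d tau / d(alpha s) shared factor: C0 xi dl El (dl r'(z) + l r(z))
        U += xi(ex_q(r) - 1) * C0 * dl * El * (dl * drelexpm1(z) + l * rz);
        gk[9 + ex_q(r) - 1] -= tau; // d/d log xi_q
        El *= 1.0 + z * rz;         // advance exp(alpha s l)
      }
      double ll_surv = -ch;
      if (ev == 1) {
        ll_surv += lxi(qT(i) - 1) + gl + alpha * (a0 + s * Tvec(i));
        gk[9 + qT(i) - 1] += 1.0;
      }
      // prior
      double qb = gi00 * b0 * b0 + 2.0 * gi01 * b0 * b1 + gi11 * b1 * b1;
      double ll_prior = -log2pi - 0.5 * ldG - 0.5 * qb;
      // gradient pieces
      double dlong_b0c = r1 / sigma2;   // d ll_long / d beta0
      double dlong_slope = rt / sigma2; // d ll_long / d gfix
      double dsurv_s = -alpha * U + (ev ? alpha * Tvec(i) : 0.0);
      double dsurv_a0 = alpha * (ev - 0.0) - alpha * ch; // ev*alpha - alpha*ch
      gk[0] = dlong_b0c + dsurv_a0;
      gk[1] = dlong_slope + dsurv_s;
      gk[2] = arm(i) * (dlong_slope + dsurv_s);
      // dprior/dG = -0.5 (Ginv - Ginv b b' Ginv), contracted with dG/dth
      double u0 = gi00 * b0 + gi01 * b1;
      double u1 = gi01 * b0 + gi11 * b1;
      double M00 = -0.5 * (gi00 - u0 * u0);
      double M01 = -0.5 * (gi01 - u0 * u1);
      double M11 = -0.5 * (gi11 - u1 * u1);
      gk[3] = M00 * dG1[0] + 2.0 * M01 * dG1[1] + M11 * dG1[2];
      gk[4] = M00 * dG2[0] + 2.0 * M01 * dG2[1] + M11 * dG2[2];
      gk[5] = M00 * dG3[0] + 2.0 * M01 * dG3[1] + M11 * dG3[2];
      gk[6] = -0.5 * d + rss / (2.0 * sigma2); // d/d log sigma2
      gk[7] = arm(i) * (ev - ch);
      gk[8] = (ev ? (a0 + s * Tvec(i)) : 0.0) - a0 * ch - s * U;
      double v = ghlw(k) + xsq(k) + M_LN2 + logdetB(i) +
        ll_long + ll_surv + ll_prior;
      bufL[k] = v;
      if (v > mx) mx = v;
    }
    if (!std::isfinite(mx))
      return List::create(_["value"] = neg_inf, _["gradient"] = grad);
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      bufL[k] = std::exp(bufL[k] - mx);
      acc += bufL[k];
    }
    ll += mx + std::log(acc);
    for (int k = 0; k < K; ++k) {
      double p = bufL[k] / acc;
      const double *gk = &g_scratch[k * P];
      for (int q = 0; q < P; ++q) grad(q) += p * gk[q];
    }
  }
  return List::create(_["value"] = ll, _["gradient"] = grad);
}
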