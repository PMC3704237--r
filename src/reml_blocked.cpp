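// Restricted log-likelihood and BLUP solutions for the first-order
// reaction-norm sire model
//
//   y = X beta + Z_s u_s + Z_d u_d + e ,   X row = sire-design row = (1, E)
//
// with u_s the per-sire (intercept, slope) effects (i.i.d. with 2x2
// covariance Gs, or correlated across sires via a numerator relationship
// matrix A), u_d the per-daughter (intercept[, slope]) effects (i.i.d.
// with covariance Gd), and e heteroscedastic-diagonal by residual class.
//
// Daughters are nested in sires and carry few records each, so the
// daughter effects and residual are absorbed daughter-by-daughter by the
// Woodbury identity on D_i = R_i + Wd_i Gd Wd_i' (at most a 2x2 solve per
// daughter, closed form).  The remaining mixed-model equations involve
// only the fixed effects and the 2q sire effects; with i.i.d. sires they
// decouple into q 2x2 blocks solved in closed form.
//
// REML identity used: log|V| + log|X' V^-1 X| = log|D| + log|G| + log|C|,
// with C the full MME coefficient matrix (fixed rows included), so
//   -2 l_R = (n-p) log(2 pi) + log|D| + log|G| + log|C| + y' P y .

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".reml_blocked_cpp")]]
Rcpp::List reml_blocked_cpp(const Rcpp::NumericVector& y,
                            const Rcpp::NumericVector& env,
                            const Rcpp::IntegerVector& d_start,  // n_d + 1, 0-based
                            const Rcpp::IntegerVector& d_sire,   // n_d, 0-based
                            const Rcpp::IntegerVector& rclass,   // n, 1-based
                            const Rcpp::NumericVector& sigma2e,  // per class
                            const Rcpp::NumericMatrix& Gs,       // 2x2
                            const Rcpp::NumericMatrix& Gd,       // 1x1 or 2x2
                            const Rcpp::NumericMatrix& Ainv,     // 0x0 => iid
                            const double logdetA,
                            const bool want_blups) {
  const int n = y.size();
  const int p = 2;
  const int nd = d_sire.size();
  const bool iid = (Ainv.nrow() == 0);
  int q = 0;
  for (int i = 0; i < nd; ++i) if (d_sire[i] + 1 > q) q = d_sire[i] + 1;
  if (!iid) q = Ainv.nrow();
  const int qd = Gd.nrow();

  // sire covariance inverse and log-determinant (2x2 closed form)
  const double gs11 = Gs(0, 0), gs12 = Gs(0, 1), gs22 = Gs(1, 1);
  const double dets = gs11 * gs22 - gs12 * gs12;
  if (dets <= 0.0 || gs11 <= 0.0)
    Rcpp::stop("sire covariance not positive definite");
  const double ld_gs = std::log(dets);
  const double gi11 = gs22 / dets, gi22 = gs11 / dets, gi12 = -gs12 / dets;

  // daughter covariance inverse and log-determinant
  const double g11 = Gd(0, 0);
  const double g12 = (qd > 1) ? Gd(0, 1) : 0.0;
  const double g22 = (qd > 1) ? Gd(1, 1) : 0.0;
  double detd, di11 = 0, di12 = 0, di22 = 0, ld_gd;
  if (qd > 1) {
    detd = g11 * g22 - g12 * g12;
    if (detd <= 0.0 || g11 <= 0.0)
      Rcpp::stop("daughter covariance not positive definite");
    di11 = g22 / detd; di22 = g11 / detd; di12 = -g12 / detd;
    ld_gd = std::log(detd);
  } else {
    if (g11 <= 0.0) Rcpp::stop("daughter variance not positive");
    di11 = 1.0 / g11;
    ld_gd = std::log(g11);
  }

  double logdetD = 0.0, yDy = 0.0;
  // per-sire accumulators of A_i = W' D^-1 W (sym: a11,a12,a22), b = W' D^-1 y
  std::vector<double> s11(q, 0.0), s12(q, 0.0), s22(q, 0.0);
  std::vector<double> rs1(q, 0.0), rs2(q, 0.0);

  for (int i = 0; i < nd; ++i) {
    const int r0 = d_start[i], r1 = d_start[i + 1];  // [r0, r1)
    const int j = d_sire[i];

    // raw weighted sums with R^-1
    double p11 = 0, p12 = 0, p22 = 0, q1 = 0, q2 = 0, qyy = 0, ldr = 0;
    for (int r = r0; r < r1; ++r) {
      const double v = sigma2e[rclass[r] - 1];
      if (v <= 0.0) Rcpp::stop("residual variance not positive");
      const double ri = 1.0 / v;
      const double e = env[r], yy = y[r];
      ldr += std::log(v);
      p11 += ri;
      p12 += ri * e;
      p22 += ri * e * e;
      q1 += ri * yy;
      q2 += ri * e * yy;
      qyy += ri * yy * yy;
    }

    double a11, a12, a22, b1, b2, ydy, ld;
    if (qd > 1) {
      // K = Gd^-1 + Wd' R^-1 Wd (2x2); |D| = |R| |Gd| |K|
      const double k11 = di11 + p11, k12 = di12 + p12, k22 = di22 + p22;
      const double detk = k11 * k22 - k12 * k12;
      if (detk <= 0.0 || k11 <= 0.0)
        Rcpp::stop("record covariance not positive definite");
      const double ki11 = k22 / detk, ki22 = k11 / detk, ki12 = -k12 / detk;
      ld = ldr + ld_gd + std::log(detk);
      // s1 = Wd'R^-1 1 = (p11,p12); s2 = Wd'R^-1 e = (p12,p22); sy = (q1,q2)
      const double c1x = ki11 * p11 + ki12 * p12, c1y = ki12 * p11 + ki22 * p12;
      const double c2x = ki11 * p12 + ki12 * p22, c2y = ki12 * p12 + ki22 * p22;
      const double cyx = ki11 * q1 + ki12 * q2,  cyy = ki12 * q1 + ki22 * q2;
      a11 = p11 - (c1x * p11 + c1y * p12);
      a12 = p12 - (c1x * p12 + c1y * p22);
      a22 = p22 - (c2x * p12 + c2y * p22);
      b1 = q1 - (c1x * q1 + c1y * q2);
      b2 = q2 - (c2x * q1 + c2y * q2);
      ydy = qyy - (cyx * q1 + cyy * q2);
    } else {
      // scalar Woodbury with Wd = 1
      const double k = di11 + p11;
      if (k <= 0.0) Rcpp::stop("record covariance not positive definite");
      const double ki = 1.0 / k;
      ld = ldr + ld_gd + std::log(k);
      a11 = p11 - ki * p11 * p11;
      a12 = p12 - ki * p11 * p12;
      a22 = p22 - ki * p12 * p12;
      b1 = q1 - ki * p11 * q1;
      b2 = q2 - ki * p12 * q1;
      ydy = qyy - ki * q1 * q1;
    }

    logdetD += ld;
    yDy += ydy;
    s11[j] += a11; s12[j] += a12; s22[j] += a22;
    rs1[j] += b1; rs2[j] += b2;
  }

  double cf11 = 0, cf12 = 0, cf22 = 0, rf1 = 0, rf2 = 0;
  for (int j = 0; j < q; ++j) {
    cf11 += s11[j]; cf12 += s12[j]; cf22 += s22[j];
    rf1 += rs1[j]; rf2 += rs2[j];
  }

  double logdetC = 0.0, logdetG, yPy;
  double beta0, beta1;
  Rcpp::NumericMatrix u(q, 2);

  if (iid) {
    logdetG = static_cast<double>(q) * ld_gs;
    double f11 = cf11, f12 = cf12, f22 = cf22, h1 = rf1, h2 = rf2;
    std::vector<double> t11(q), t12(q), t22(q);
    for (int j = 0; j < q; ++j) {
      const double m11 = s11[j] + gi11;
      const double m12 = s12[j] + gi12;
      const double m22 = s22[j] + gi22;
      const double det = m11 * m22 - m12 * m12;
      if (det <= 0.0 || m11 <= 0.0)
        Rcpp::stop("sire MME block not positive definite");
      logdetC += std::log(det);
      const double i11 = m22 / det, i22 = m11 / det, i12 = -m12 / det;
      t11[j] = i11; t12[j] = i12; t22[j] = i22;
      const double p11s = s11[j] * i11 + s12[j] * i12;
      const double p12s = s11[j] * i12 + s12[j] * i22;
      const double p21s = s12[j] * i11 + s22[j] * i12;
      const double p22s = s12[j] * i12 + s22[j] * i22;
      f11 -= p11s * s11[j] + p12s * s12[j];
      f12 -= p11s * s12[j] + p12s * s22[j];
      f22 -= p21s * s12[j] + p22s * s22[j];
      h1 -= p11s * rs1[j] + p12s * rs2[j];
      h2 -= p21s * rs1[j] + p22s * rs2[j];
    }
    const double detF = f11 * f22 - f12 * f12;
    if (detF <= 0.0 || f11 <= 0.0)
      Rcpp::stop("fixed-effect equations singular");
    logdetC += std::log(detF);
    beta0 = (f22 * h1 - f12 * h2) / detF;
    beta1 = (-f12 * h1 + f11 * h2) / detF;
    for (int j = 0; j < q; ++j) {
      const double z1 = rs1[j] - (s11[j] * beta0 + s12[j] * beta1);
      const double z2 = rs2[j] - (s12[j] * beta0 + s22[j] * beta1);
      u(j, 0) = t11[j] * z1 + t12[j] * z2;
      u(j, 1) = t12[j] * z1 + t22[j] * z2;
    }
  } else {
    logdetG = static_cast<double>(q) * ld_gs + 2.0 * logdetA;
    const int dim = p + 2 * q;
    arma::mat C(dim, dim, arma::fill::zeros);
    arma::vec rhs(dim, arma::fill::zeros);
    C(0, 0) = cf11; C(0, 1) = cf12; C(1, 0) = cf12; C(1, 1) = cf22;
    rhs[0] = rf1; rhs[1] = rf2;
    for (int j = 0; j < q; ++j) {
      C(0, p + 2 * j) = C(p + 2 * j, 0) = s11[j];
      C(0, p + 2 * j + 1) = C(p + 2 * j + 1, 0) = s12[j];
      C(1, p + 2 * j) = C(p + 2 * j, 1) = s12[j];
      C(1, p + 2 * j + 1) = C(p + 2 * j + 1, 1) = s22[j];
      rhs[p + 2 * j] = rs1[j];
      rhs[p + 2 * j + 1] = rs2[j];
    }
    for (int j = 0; j < q; ++j) {
      for (int k = 0; k < q; ++k) {
        const double a = Ainv(j, k);
        C(p + 2 * j, p + 2 * k) += a * gi11;
        C(p + 2 * j, p + 2 * k + 1) += a * gi12;
        C(p + 2 * j + 1, p + 2 * k) += a * gi12;
        C(p + 2 * j + 1, p + 2 * k + 1) += a * gi22;
      }
      C(p + 2 * j, p + 2 * j) += s11[j];
      C(p + 2 * j, p + 2 * j + 1) += s12[j];
      C(p + 2 * j + 1, p + 2 * j) += s12[j];
      C(p + 2 * j + 1, p + 2 * j + 1) += s22[j];
    }
    arma::mat Lc;
    if (!arma::chol(Lc, C, "lower"))
      Rcpp::stop("mixed-model equations singular");
    logdetC = 2.0 * arma::accu(arma::log(Lc.diag()));
    arma::vec sol = arma::solve(arma::trimatu(Lc.t()),
                                arma::solve(arma::trimatl(Lc), rhs));
    beta0 = sol[0]; beta1 = sol[1];
    for (int j = 0; j < q; ++j) {
      u(j, 0) = sol[p + 2 * j];
      u(j, 1) = sol[p + 2 * j + 1];
    }
  }

  yPy = yDy - (beta0 * rf1 + beta1 * rf2);
  for (int j = 0; j < q; ++j) {
    yPy -= u(j, 0) * rs1[j] + u(j, 1) * rs2[j];
  }

  const double loglik = -0.5 * (static_cast<double>(n - p) * std::log(2.0 * M_PI)
                                + logdetD + logdetG + logdetC + yPy);

  if (want_blups) {
    return Rcpp::List::create(
        Rcpp::Named("loglik") = loglik,
        Rcpp::Named("beta") = Rcpp::NumericVector::create(beta0, beta1),
        Rcpp::Named("u") = u);
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = loglik);
}
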