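#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// All randomness comes from R's RNG (norm_rand / R::rchisq) so that
// set.seed() in R makes entire chains bitwise reproducible.

// Scaled-inverse-chi-square: (ss + prior_ss) / chisq(df + prior_df)
static inline double rsinvchi2(double df, double ss) {
  return ss / R::rchisq(df);
}

// 2x2 inverse-Wishart draw with scale S and degrees of freedom nu,
// via Bartlett decomposition of the Wishart(nu, S^-1) companion.
// Retries with a small ridge if S is numerically indefinite.
static arma::mat riwish2(arma::mat S, double nu) {
  arma::mat L;
  int tries = 0;
  while (!arma::chol(L, arma::inv_sympd(arma::symmatu(S)), "lower")) {
    S.diag() += 1e-8 * (1.0 + arma::trace(S));
    if (++tries > 10) stop("inverse-Wishart scale matrix is not positive definite");
  }
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(nu));
  A(1, 1) = std::sqrt(R::rchisq(nu - 1.0));
  A(1, 0) = norm_rand();
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();           // Wishart(nu, S^-1)
  return arma::inv_sympd(arma::symmatu(W));
}

// Meuwissen & Luo (1992) inbreeding coefficients.
// sire/dam are 1-based renumbered ids, 0 = unknown; parents precede offspring.
// [[Rcpp::export]]
NumericVector inbreeding_ml_cpp(IntegerVector sire, IntegerVector dam) {
  int q = sire.size();
  std::vector<double> F(q, 0.0), D(q, 0.0), L(q, 0.0);
  for (int i = 0; i < q; ++i) {
    int s = sire[i], d = dam[i];
    double Fs = s > 0 ? F[s - 1] : -1.0;
    double Fd = d > 0 ? F[d - 1] : -1.0;
    D[i] = 0.5 - 0.25 * (Fs + Fd);     // Mendelian sampling variance share
    if (s == 0 || d == 0) { F[i] = 0.0; continue; }
    // a_ii = sum over ancestors of L_j^2 D_j; F_i = a_ii - 1
    double aii = 0.0;
    L[i] = 1.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      int sj = sire[j], dj = dam[j];
      if (sj > 0) L[sj - 1] += 0.5 * L[j];
      if (dj > 0) L[dj - 1] += 0.5 * L[j];
      aii += L[j] * L[j] * D[j];
      L[j] = 0.0;
    }
    F[i] = aii - 1.0;
  }
  return wrap(F);
}

// Dot product of sparse-matrix column `col` with dense vector v, plus the
// diagonal entry of that column, in one pass.
static inline void spcol_dot(const arma::sp_mat& M, int col, const arma::vec& v,
                             double& dot, double& diag) {
  dot = 0.0; diag = 0.0;
  for (arma::sp_mat::const_col_iterator it = M.begin_col(col); it != M.end_col(col); ++it) {
    dot += (*it) * v(it.row());
    if ((int)it.row() == col) diag = *it;
  }
}

// Univariate single-site Gibbs sampler for animal models
//   M1: y = Xb + Zu + e
//   M2: y = Xb + Zu + Wd + e            (cov(u,d) = A sigma_am)
//   M3: y = Xb + Zu + Wd + Mpe + e
// Design W here is the full location incidence [X Z (W) (M)], C0 = W'W.
// Location effects are sampled one at a time from their normal full
// conditionals; variances from scaled-inverse-chi-square / 2x2
// inverse-Wishart full conditionals.
// [[Rcpp::export]]
List gibbs_uni_cpp(const arma::vec& y,
                   const arma::sp_mat& W,
                   const arma::sp_mat& C0,
                   const arma::vec& rhs,
                   const arma::sp_mat& Ainv,
                   int p, int q, bool has_mat, bool has_pe, int nd,
                   int n_iter, int burn, int thin,
                   List prior, List start) {
  const int n = y.n_elem;
  const int m = C0.n_cols;
  // priors: scalar components carry df and df*scale (added to SS);
  // the 2x2 genetic prior carries a scale matrix Vg and df nu_g.
  const double nu_a = as<double>(prior["nu_a"]),  ssa = as<double>(prior["ss_a"]);
  const double nu_pe = as<double>(prior["nu_pe"]), sspe = as<double>(prior["ss_pe"]);
  const double nu_e = as<double>(prior["nu_e"]),  sse = as<double>(prior["ss_e"]);
  const arma::mat Vg = as<arma::mat>(prior["Vg"]);
  const double nu_g = as<double>(prior["nu_g"]);

  double s2a = as<double>(start["sigma2_a"]);
  double s2m = has_mat ? as<double>(start["sigma2_m"]) : 0.0;
  double sam = has_mat ? as<double>(start["sigma_am"]) : 0.0;
  double s2pe = has_pe ? as<double>(start["sigma2_pe"]) : 0.0;
  double s2e = as<double>(start["sigma2_e"]);
  const double s2e0 = s2e;

  arma::vec theta(m, arma::fill::zeros);
  const int nkeep = (n_iter - burn) / thin;
  arma::mat draws(nkeep, 5, arma::fill::zeros);
  arma::vec deviance(nkeep, arma::fill::zeros);
  arma::vec theta_sum(m, arma::fill::zeros);
  double s2e_sum = 0.0;
  int kept = 0;

  const double LOG2PI = std::log(2.0 * M_PI);

  for (int iter = 1; iter <= n_iter; ++iter) {
    // G^-1 elements (per-iteration scalars folded into the sweep)
    double gi11, gi12 = 0.0, gi22 = 0.0;
    if (has_mat) {
      double det = s2a * s2m - sam * sam;
      gi11 = s2m / det; gi22 = s2a / det; gi12 = -sam / det;
    } else {
      gi11 = 1.0 / s2a;
    }

    // --- location effects, single site ---
    for (int i = 0; i < m; ++i) {
      double cdot, cdiag;
      spcol_dot(C0, i, theta, cdot, cdiag);
      double num = rhs(i) - (cdot - cdiag * theta(i));
      double den = cdiag;
      if (i >= p && i < p + q) {              // direct breeding value u_k
        int k = i - p;
        double au = 0.0, akk = 0.0, ad = 0.0;
        for (arma::sp_mat::const_col_iterator it = Ainv.begin_col(k); it != Ainv.end_col(k); ++it) {
          au += (*it) * theta(p + it.row());
          if (has_mat) ad += (*it) * theta(p + q + it.row());
          if ((int)it.row() == k) akk = *it;
        }
        num -= s2e * (gi11 * (au - akk * theta(i)) + gi12 * ad);
        den += s2e * gi11 * akk;
      } else if (has_mat && i >= p + q && i < p + 2 * q) {   // maternal value d_k
        int k = i - p - q;
        double ad = 0.0, akk = 0.0, au = 0.0;
        for (arma::sp_mat::const_col_iterator it = Ainv.begin_col(k); it != Ainv.end_col(k); ++it) {
          au += (*it) * theta(p + it.row());
          ad += (*it) * theta(p + q + it.row());
          if ((int)it.row() == k) akk = *it;
        }
        num -= s2e * (gi22 * (ad - akk * theta(i)) + gi12 * au);
        den += s2e * gi22 * akk;
      } else if (has_pe && i >= m - nd) {     // permanent environment of dam
        den += s2e / s2pe;
      }
      theta(i) = num / den + std::sqrt(s2e / den) * norm_rand();
    }

    // --- variance components ---
    const arma::vec u = theta.subvec(p, p + q - 1);
    if (has_mat) {
      const arma::vec d = theta.subvec(p + q, p + 2 * q - 1);
      arma::vec Au = Ainv * u, Ad = Ainv * d;
      arma::mat Sw = Vg;
      Sw(0, 0) += arma::dot(u, Au);
      Sw(0, 1) += arma::dot(u, Ad);
      Sw(1, 0) = Sw(0, 1);
      Sw(1, 1) += arma::dot(d, Ad);
      arma::mat G = riwish2(Sw, (double)q + nu_g);
      s2a = G(0, 0); s2m = G(1, 1); sam = G(0, 1);
    } else {
      double uAu = arma::dot(u, Ainv * u);
      s2a = rsinvchi2((double)q + nu_a, uAu + ssa);
    }
    if (has_pe) {
      const arma::vec pe = theta.subvec(m - nd, m - 1);
      s2pe = rsinvchi2((double)nd + nu_pe, arma::dot(pe, pe) + sspe);
    }
    arma::vec e = y - W * theta;
    s2e = rsinvchi2((double)n + nu_e, arma::dot(e, e) + sse);
    if (!std::isfinite(s2e) || s2e > 1e12 * s2e0)
      stop("residual variance diverged at iteration %d", iter);

    if (iter > burn && (iter - burn) % thin == 0) {
      draws(kept, 0) = s2a;
      draws(kept, 1) = s2m;
      draws(kept, 2) = sam;
      draws(kept, 3) = s2pe;
      draws(kept, 4) = s2e;
      deviance(kept) = n * (LOG2PI + std::log(s2e)) + arma::dot(e, e) / s2e;
      theta_sum += theta;
      s2e_sum += s2e;
      ++kept;
    }
  }

  arma::vec theta_bar = theta_sum / std::max(kept, 1);
  double s2e_bar = s2e_sum / std::max(kept, 1);
  arma::vec e_bar = y - W * theta_bar;
  double d_at_mean = n * (LOG2PI + std::log(s2e_bar)) + arma::dot(e_bar, e_bar) / s2e_bar;

  return List::create(_["draws"] = draws,
                      _["deviance"] = deviance,
                      _["theta_mean"] = theta_bar,
                      _["sigma2_e_mean"] = s2e_bar,
                      _["d_at_mean"] = d_at_mean);
}

// Bivariate animal model (direct additive effects only, M1 structure per
// trait) with residual covariance; missing records for one trait are
// imputed by data augmentation from the conditional residual distribution.
// Rows where both traits are missing must be removed beforehand.
// [[Rcpp::export]]
List gibbs_biv_cpp(arma::vec y1, arma::vec y2,
                   const arma::ivec& obs1, const arma::ivec& obs2,
                   const arma::sp_mat& W,
                   const arma::sp_mat& C0,
                   const arma::sp_mat& Ainv,
                   int p, int q,
                   int n_iter, int burn, int thin,
                   List prior, List start) {
  const int n = y1.n_elem;
  const int m = C0.n_cols;
  const arma::mat Vg = as<arma::mat>(prior["Vg"]);
  const double nu_g = as<double>(prior["nu_g"]);
  const arma::mat Vr = as<arma::mat>(prior["Vr"]);
  const double nu_r = as<double>(prior["nu_r"]);

  arma::mat G0 = as<arma::mat>(start["G0"]);
  arma::mat R0 = as<arma::mat>(start["R0"]);

  arma::vec th1(m, arma::fill::zeros), th2(m, arma::fill::zeros);
  const int nkeep = (n_iter - burn) / thin;
  arma::mat draws(nkeep, 8, arma::fill::zeros);   // g11 g22 g12 r11 r22 r12 rg re
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- augment missing records ---
    arma::vec f1 = W * th1, f2 = W * th2;
    for (int i = 0; i < n; ++i) {
      if (!obs1(i)) {
        double cm = f1(i) + R0(0, 1) / R0(1, 1) * (y2(i) - f2(i));
        double cv = R0(0, 0) - R0(0, 1) * R0(0, 1) / R0(1, 1);
        y1(i) = cm + std::sqrt(cv) * norm_rand();
      }
      if (!obs2(i)) {
        double cm = f2(i) + R0(0, 1) / R0(0, 0) * (y1(i) - f1(i));
        double cv = R0(1, 1) - R0(0, 1) * R0(0, 1) / R0(0, 0);
        y2(i) = cm + std::sqrt(cv) * norm_rand();
      }
    }
    arma::vec rhs1 = arma::vec(W.t() * y1), rhs2 = arma::vec(W.t() * y2);

    double detR = R0(0, 0) * R0(1, 1) - R0(0, 1) * R0(0, 1);
    double r11 = R0(1, 1) / detR, r22 = R0(0, 0) / detR, r12 = -R0(0, 1) / detR;
    double detG = G0(0, 0) * G0(1, 1) - G0(0, 1) * G0(0, 1);
    double g11 = G0(1, 1) / detG, g22 = G0(0, 0) / detG, g12 = -G0(0, 1) / detG;

    // --- location effects: for each column, trait 1 then trait 2 ---
    for (int i = 0; i < m; ++i) {
      double cdot1, cdot2, cdiag;
      spcol_dot(C0, i, th1, cdot1, cdiag);
      spcol_dot(C0, i, th2, cdot2, cdiag);
      double au1 = 0.0, au2 = 0.0, akk = 0.0;
      bool is_u = (i >= p);
      if (is_u) {
        int k = i - p;
        for (arma::sp_mat::const_col_iterator it = Ainv.begin_col(k); it != Ainv.end_col(k); ++it) {
          au1 += (*it) * th1(p + it.row());
          au2 += (*it) * th2(p + it.row());
          if ((int)it.row() == k) akk = *it;
        }
      }
      // trait 1
      {
        double num = r11 * (rhs1(i) - (cdot1 - cdiag * th1(i))) + r12 * (rhs2(i) - cdot2);
        double den = r11 * cdiag;
        if (is_u) {
          num -= g11 * (au1 - akk * th1(i)) + g12 * au2;
          den += g11 * akk;
        }
        double old = th1(i);
        th1(i) = num / den + norm_rand() / std::sqrt(den);
        cdot1 += cdiag * (th1(i) - old);
        if (is_u) au1 += akk * (th1(i) - old);
      }
      // trait 2
      {
        double num = r22 * (rhs2(i) - (cdot2 - cdiag * th2(i))) + r12 * (rhs1(i) - cdot1);
        double den = r22 * cdiag;
        if (is_u) {
          num -= g22 * (au2 - akk * th2(i)) + g12 * au1;
          den += g22 * akk;
        }
        th2(i) = num / den + norm_rand() / std::sqrt(den);
      }
    }

    // --- covariance matrices ---
    arma::vec u1 = th1.subvec(p, p + q - 1), u2 = th2.subvec(p, p + q - 1);
    arma::vec Au1 = Ainv * u1, Au2 = Ainv * u2;
    arma::mat Sg = Vg;
    Sg(0, 0) += arma::dot(u1, Au1);
    Sg(0, 1) += arma::dot(u1, Au2);
    Sg(1, 0) = Sg(0, 1);
    Sg(1, 1) += arma::dot(u2, Au2);
    G0 = riwish2(Sg, (double)q + nu_g);

    arma::vec e1 = y1 - W * th1, e2 = y2 - W * th2;
    arma::mat Sr = Vr;
    Sr(0, 0) += arma::dot(e1, e1);
    Sr(0, 1) += arma::dot(e1, e2);
    Sr(1, 0) = Sr(0, 1);
    Sr(1, 1) += arma::dot(e2, e2);
    R0 = riwish2(Sr, (double)n + nu_r);

    if (iter > burn && (iter - burn) % thin == 0) {
      draws(kept, 0) = G0(0, 0);
      draws(kept, 1) = G0(1, 1);
      draws(kept, 2) = G0(0, 1);
      draws(kept, 3) = R0(0, 0);
      draws(kept, 4) = R0(1, 1);
      draws(kept, 5) = R0(0, 1);
      draws(kept, 6) = G0(0, 1) / std::sqrt(G0(0, 0) * G0(1, 1));
      draws(kept, 7) = R0(0, 1) / std::sqrt(R0(0, 0) * R0(1, 1));
      ++kept;
    }
  }

  return List::create(_["draws"] = draws);
}
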