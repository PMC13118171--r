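// Adaptive Metropolis-within-Gibbs sampler for cluster-level beta-binomial
// prevalence models:
//   Y_c | p_c ~ BetaBinomial(n_c, p_c, d)
//   logit(p_c) = [alpha | alpha_{a[c]}] + [gamma | gamma_{a[c]}] 1{c rural}
//                + x_c' beta + u_{i[c]}
// with u the BYM2 effect sigma * (sqrt(1-phi) e1 + sqrt(phi) e2), e2 a scaled
// ICAR field with a soft sum-to-zero constraint per graph component, PC priors
// on sigma and phi (phi prior tabulated on a grid), and a truncated
// exponential prior on the overdispersion d.

#include <Rcpp.h>
using namespace Rcpp;

static const double VAGUE_SD = 31.6;

// beta-binomial log pmf without the lchoose(n, Y) constant
static inline double bb_ll(int Y, int n, double eta, double d) {
  double p = 1.0 / (1.0 + std::exp(-eta));
  if (p < 1e-12) p = 1e-12;
  if (p > 1 - 1e-12) p = 1 - 1e-12;
  if (d < 1e-12) {
    return Y * std::log(p) + (n - Y) * std::log1p(-p);
  }
  double a = p * (1 - d) / d;
  double b = (1 - p) * (1 - d) / d;
  return R::lbeta(Y + a, n - Y + b) - R::lbeta(a, b);
}

struct Adapt {
  std::vector<double> lstep;
  Adapt(int n, double init) : lstep(n, std::log(init)) {}
  double step(int i) const { return std::exp(lstep[i]); }
  void tune(int i, double acc_prob, int it, double target = 0.44) {
    double g = std::min(0.1, 1.0 / std::sqrt((double)it));
    lstep[i] += g * (acc_prob - target);
    if (lstep[i] > 3) lstep[i] = 3;
    if (lstep[i] < -8) lstep[i] = -8;
  }
};

static inline double interp_logdens(const NumericVector& grid,
                                    const NumericVector& ld, double x) {
  int K = grid.size();
  if (x <= grid[0]) return ld[0];
  if (x >= grid[K - 1]) return ld[K - 1];
  int lo = (int)((x - grid[0]) / (grid[1] - grid[0]));
  if (lo < 0) lo = 0;
  if (lo > K - 2) lo = K - 2;
  double t = (x - grid[lo]) / (grid[lo + 1] - grid[lo]);
  return ld[lo] * (1 - t) + ld[lo + 1] * t;
}

// [[Rcpp::export]]
List bb_mcmc_cpp(IntegerVector Y, IntegerVector n, IntegerVector rural,
                 IntegerVector a1, IntegerVector a2, NumericMatrix X,
                 int n_admin1, int n_area,
                 List nb, NumericVector area_scale, IntegerVector comp,
                 LogicalVector singleton,
                 int alpha_mode, int gamma_mode, int use_re,
                 int intercept_logistic,
                 double lambda_sigma,
                 NumericVector phi_grid, NumericVector phi_logdens,
                 double lambda_d, double fix_d, double fix_sigma,
                 double fix_phi,
                 int n_iter, int burn_in) {
  int C = Y.size();
  int p = X.ncol();
  int nA = (alpha_mode == 1) ? n_admin1 : 1;
  int nG = (gamma_mode == 0) ? 0 : ((gamma_mode == 2) ? n_admin1 : 1);
  int n_comp = 0;
  for (int i = 0; i < n_area; ++i) if (comp[i] + 1 > n_comp) n_comp = comp[i] + 1;

  // index lists
  std::vector<std::vector<int>> cl_of_area(n_area), cl_of_a1(n_admin1);
  for (int c = 0; c < C; ++c) {
    if (use_re) cl_of_area[a2[c]].push_back(c);
    cl_of_a1[a1[c]].push_back(c);
  }
  std::vector<std::vector<int>> nbv(n_area);
  for (int i = 0; i < n_area; ++i) {
    IntegerVector v = nb[i];
    for (int k = 0; k < v.size(); ++k) nbv[i].push_back(v[k]);
  }
  std::vector<int> comp_size(n_comp, 0);
  for (int i = 0; i < n_area; ++i) comp_size[comp[i]]++;

  // state
  std::vector<double> alpha(nA, 0.0), gamma(std::max(nG, 1), 0.0),
      beta(std::max(p, 1), 0.0), e1(n_area, 0.0), e2(n_area, 0.0),
      u(n_area, 0.0);
  double sigma = (fix_sigma >= 0) ? fix_sigma : 0.3;
  double phi = (fix_phi >= 0) ? fix_phi : 0.5;
  double d = (fix_d >= 0) ? fix_d : 0.1;

  std::vector<double> xb(C, 0.0), eta(C), ll(C);
  std::vector<double> comp_sum(n_comp, 0.0);
  // soft sum-to-zero: component sums ~ N(0, 0.001 * m_k)
  std::vector<double> kappa(n_comp);
  for (int k = 0; k < n_comp; ++k) kappa[k] = 1.0 / (0.001 * comp_size[k]);

  auto u_of = [&](int i) {
    if (singleton[i]) return sigma * e1[i];
    return sigma * (std::sqrt(1 - phi) * e1[i] + std::sqrt(phi) * e2[i]);
  };
  auto eta_of = [&](int c) {
    double v = alpha[alpha_mode == 1 ? a1[c] : 0];
    if (gamma_mode > 0 && rural[c])
      v += gamma[gamma_mode == 2 ? a1[c] : 0];
    v += xb[c];
    if (use_re) v += u[a2[c]];
    return v;
  };
  auto refresh_all = [&]() {
    for (int i = 0; i < n_area; ++i) u[i] = u_of(i);
    for (int c = 0; c < C; ++c) {
      eta[c] = eta_of(c);
      ll[c] = bb_ll(Y[c], n[c], eta[c], d);
    }
  };
  refresh_all();

  auto ll_sum_of = [&](const std::vector<int>& idx, double delta_eta,
                       double dd) {
    double s = 0;
    for (int c : idx) s += bb_ll(Y[c], n[c], eta[c] + delta_eta, dd);
    return s;
  };
  auto ll_cur_of = [&](const std::vector<int>& idx) {
    double s = 0;
    for (int c : idx) s += ll[c];
    return s;
  };
  auto apply_delta = [&](const std::vector<int>& idx, double delta_eta,
                         double dd) {
    for (int c : idx) {
      eta[c] += delta_eta;
      ll[c] = bb_ll(Y[c], n[c], eta[c], dd);
    }
  };

  double lsig_step = 0.3, lphi_step = 0.5, ld_step = 0.4;
  Adapt ad_alpha(nA, 0.1), ad_gamma(std::max(nG, 1), 0.1),
      ad_beta(std::max(p, 1), 0.05), ad_e1(n_area, 0.3), ad_e2(n_area, 0.3);

  int n_keep = n_iter - burn_in;
  NumericMatrix keep_alpha(n_keep, nA);
  NumericMatrix keep_gamma(n_keep, std::max(nG, 0));
  NumericMatrix keep_beta(n_keep, p);
  NumericMatrix keep_u(n_keep, use_re ? n_area : 0);
  NumericVector keep_sigma(n_keep), keep_phi(n_keep), keep_d(n_keep);
  double acc_hyper = 0, n_hyper = 0;

  std::vector<int> all_idx(C);
  for (int c = 0; c < C; ++c) all_idx[c] = c;

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    // ---- alpha ----
    for (int aix = 0; aix < nA; ++aix) {
      const std::vector<int>& idx = (alpha_mode == 1) ? cl_of_a1[aix] : all_idx;
      double st = ad_alpha.step(aix);
      double prop = R::norm_rand() * st;
      double lp0, lp1;
      if (intercept_logistic && alpha_mode == 0) {
        double a0 = alpha[aix], a1v = alpha[aix] + prop;
        lp0 = a0 - 2 * std::log1p(std::exp(a0));
        lp1 = a1v - 2 * std::log1p(std::exp(a1v));
      } else {
        lp0 = -0.5 * alpha[aix] * alpha[aix] / (VAGUE_SD * VAGUE_SD);
        double a1v = alpha[aix] + prop;
        lp1 = -0.5 * a1v * a1v / (VAGUE_SD * VAGUE_SD);
      }
      double lr = ll_sum_of(idx, prop, d) - ll_cur_of(idx) + lp1 - lp0;
      double ap = std::min(1.0, std::exp(lr));
      if (R::unif_rand() < ap) {
        alpha[aix] += prop;
        apply_delta(idx, prop, d);
      }
      if (it <= burn_in) ad_alpha.tune(aix, ap, it);
    }
    // ---- gamma ----
    for (int gix = 0; gix < nG; ++gix) {
      std::vector<int> idx;
      const std::vector<int>& base = (gamma_mode == 2) ? cl_of_a1[gix] : all_idx;
      for (int c : base) if (rural[c]) idx.push_back(c);
      if (idx.empty()) continue;
      double st = ad_gamma.step(gix);
      double prop = R::norm_rand() * st;
      double g0 = gamma[gix], g1 = gamma[gix] + prop;
      double lr = ll_sum_of(idx, prop, d) - ll_cur_of(idx) -
                  0.5 * (g1 * g1 - g0 * g0) / (VAGUE_SD * VAGUE_SD);
      double ap = std::min(1.0, std::exp(lr));
      if (R::unif_rand() < ap) {
        gamma[gix] += prop;
        apply_delta(idx, prop, d);
      }
      if (it <= burn_in) ad_gamma.tune(gix, ap, it);
    }
    // ---- beta ----
    for (int j = 0; j < p; ++j) {
      double st = ad_beta.step(j);
      double prop = R::norm_rand() * st;
      double lnew = 0;
      for (int c = 0; c < C; ++c)
        lnew += bb_ll(Y[c], n[c], eta[c] + prop * X(c, j), d);
      double b0 = beta[j], b1 = beta[j] + prop;
      double lr = lnew - ll_cur_of(all_idx) -
                  0.5 * (b1 * b1 - b0 * b0) / (VAGUE_SD * VAGUE_SD);
      double ap = std::min(1.0, std::exp(lr));
      if (R::unif_rand() < ap) {
        beta[j] += prop;
        for (int c = 0; c < C; ++c) {
          xb[c] += prop * X(c, j);
          eta[c] += prop * X(c, j);
          ll[c] = bb_ll(Y[c], n[c], eta[c], d);
        }
      }
      if (it <= burn_in) ad_beta.tune(j, ap, it);
    }
    // ---- random effects ----
    if (use_re) {
      for (int i = 0; i < n_area; ++i) {
        const std::vector<int>& idx = cl_of_area[i];
        // e1 (iid)
        {
          double st = ad_e1.step(i);
          double prop = R::norm_rand() * st;
          double scale_u = singleton[i] ? sigma : sigma * std::sqrt(1 - phi);
          double de = scale_u * prop;
          double x0 = e1[i], x1 = e1[i] + prop;
          double lr = ll_sum_of(idx, de, d) - ll_cur_of(idx) -
                      0.5 * (x1 * x1 - x0 * x0);
          double ap = std::min(1.0, std::exp(lr));
          if (R::unif_rand() < ap) {
            e1[i] = x1;
            u[i] += de;
            apply_delta(idx, de, d);
          }
          if (it <= burn_in) ad_e1.tune(i, ap, it);
        }
        // e2 (scaled ICAR with soft sum-to-zero)
        if (!singleton[i]) {
          double st = ad_e2.step(i);
          double prop = R::norm_rand() * st;
          double de = sigma * std::sqrt(phi) * prop;
          double x0 = e2[i], x1 = e2[i] + prop;
          double s = area_scale[i];
          double deg = (double)nbv[i].size();
          double nbsum = 0;
          for (int jn : nbv[i]) nbsum += e2[jn];
          double lp_icar = -0.5 * s * (deg * (x1 * x1 - x0 * x0) -
                                       2 * (x1 - x0) * nbsum);
          int k = comp[i];
          double s0 = comp_sum[k], s1 = comp_sum[k] + prop;
          double lp_soft = -0.5 * kappa[k] * (s1 * s1 - s0 * s0);
          double lr = ll_sum_of(idx, de, d) - ll_cur_of(idx) + lp_icar + lp_soft;
          double ap = std::min(1.0, std::exp(lr));
          if (R::unif_rand() < ap) {
            e2[i] = x1;
            comp_sum[k] = s1;
            u[i] += de;
            apply_delta(idx, de, d);
          }
          if (it <= burn_in) ad_e2.tune(i, ap, it);
        }
      }
      // ---- sigma ----
      if (fix_sigma < 0) {
        double lsig = std::log(sigma);
        double prop = lsig + lsig_step * R::norm_rand();
        double snew = std::exp(prop);
        double lnew = 0;
        for (int c = 0; c < C; ++c) {
          double un = (snew / sigma) * u[a2[c]];
          lnew += bb_ll(Y[c], n[c], eta[c] - u[a2[c]] + un, d);
        }
        double lr = lnew - ll_cur_of(all_idx) - lambda_sigma * (snew - sigma) +
                    (prop - lsig);
        double ap = std::min(1.0, std::exp(lr));
        n_hyper += 1;
        if (R::unif_rand() < ap) {
          acc_hyper += 1;
          double ratio = snew / sigma;
          sigma = snew;
          for (int i = 0; i < n_area; ++i) u[i] *= ratio;
          for (int c = 0; c < C; ++c) {
            eta[c] = eta_of(c);
            ll[c] = bb_ll(Y[c], n[c], eta[c], d);
          }
        }
        if (it <= burn_in)
          lsig_step = std::exp(std::log(lsig_step) +
                               std::min(0.1, 1.0 / std::sqrt((double)it)) * (ap - 0.3));
      }
      // ---- phi ----
      if (fix_phi < 0) {
        double lphi = std::log(phi / (1 - phi));
        double prop = lphi + lphi_step * R::norm_rand();
        double pnew = 1 / (1 + std::exp(-prop));
        double lnew = 0;
        for (int c = 0; c < C; ++c) {
          int i = a2[c];
          double un = singleton[i] ? sigma * e1[i]
              : sigma * (std::sqrt(1 - pnew) * e1[i] + std::sqrt(pnew) * e2[i]);
          lnew += bb_ll(Y[c], n[c], eta[c] - u[i] + un, d);
        }
        double lp1 = interp_logdens(phi_grid, phi_logdens, pnew) +
                     std::log(pnew * (1 - pnew));
        double lp0 = interp_logdens(phi_grid, phi_logdens, phi) +
                     std::log(phi * (1 - phi));
        double lr = lnew - ll_cur_of(all_idx) + lp1 - lp0;
        double ap = std::min(1.0, std::exp(lr));
        if (R::unif_rand() < ap) {
          phi = pnew;
          for (int i = 0; i < n_area; ++i) u[i] = u_of(i);
          for (int c = 0; c < C; ++c) {
            eta[c] = eta_of(c);
            ll[c] = bb_ll(Y[c], n[c], eta[c], d);
          }
        }
        if (it <= burn_in)
          lphi_step = std::exp(std::log(lphi_step) +
                               std::min(0.1, 1.0 / std::sqrt((double)it)) * (ap - 0.3));
      }
    }
    // ---- d ----
    if (fix_d < 0) {
      double ld = std::log(d / (1 - d));
      double prop = ld + ld_step * R::norm_rand();
      double dn = 1 / (1 + std::exp(-prop));
      double lnew = 0;
      for (int c = 0; c < C; ++c) lnew += bb_ll(Y[c], n[c], eta[c], dn);
      // truncated exponential prior on (0,1) + logit Jacobian
      double lr = lnew - ll_cur_of(all_idx) - lambda_d * (dn - d) +
                  std::log(dn * (1 - dn)) - std::log(d * (1 - d));
      double ap = std::min(1.0, std::exp(lr));
      if (R::unif_rand() < ap) {
        d = dn;
        for (int c = 0; c < C; ++c) ll[c] = bb_ll(Y[c], n[c], eta[c], d);
      }
      if (it <= burn_in)
        ld_step = std::exp(std::log(ld_step) +
                           std::min(0.1, 1.0 / std::sqrt((double)it)) * (ap - 0.3));
    }

    if (it > burn_in) {
      int s = it - burn_in - 1;
      for (int aix = 0; aix < nA; ++aix) keep_alpha(s, aix) = alpha[aix];
      for (int g = 0; g < nG; ++g) keep_gamma(s, g) = gamma[g];
      for (int j = 0; j < p; ++j) keep_beta(s, j) = beta[j];
      if (use_re) for (int i = 0; i < n_area; ++i) keep_u(s, i) = u[i];
      keep_sigma[s] = sigma;
      keep_phi[s] = phi;
      keep_d[s] = d;
    }
  }

  return List::create(
      _["alpha"] = keep_alpha, _["gamma"] = keep_gamma, _["beta"] = keep_beta,
      _["u"] = keep_u, _["sigma"] = keep_sigma, _["phi"] = keep_phi,
      _["d"] = keep_d,
      _["accept_sigma"] = (n_hyper > 0) ? acc_hyper / n_hyper : NA_REAL);
}
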