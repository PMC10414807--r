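#include <Rcpp.h>
using namespace Rcpp;

// Spike-and-slab Gibbs sampler with an allele-frequency coupling exponent S.
//
// Model: y = Q alpha + sum_j x_j beta_j + e,
//   beta_j ~ pi1 * N(0, sigma_b2 * v_j^S) + (1 - pi1) * delta_0,
//   v_j = 2 p_j (1 - p_j) computed on the unpruned panel,
//   e ~ N(0, sigma_e2).
// S has a N(0, s_prior_sd^2) prior and is updated by random-walk Metropolis;
// sigma_b2 and sigma_e2 carry scaled inverse chi-square priors; pi1 ~ Beta(1,1).
//
// X must be column-centered; Q holds the intercept and any covariates (PCs).


// lower-triangular Cholesky of column-major k x k matrix (in place);
// returns false if not positive definite
static bool chol_lower(std::vector<double>& M, int k) {
  for (int j = 0; j < k; ++j) {
    double d = M[j + j * k];
    for (int p = 0; p < j; ++p) d -= M[j + p * k] * M[j + p * k];
    if (d <= 0.0) return false;
    double Ljj = std::sqrt(d);
    M[j + j * k] = Ljj;
    for (int i = j + 1; i < k; ++i) {
      double s = M[i + j * k];
      for (int p = 0; p < j; ++p) s -= M[i + p * k] * M[j + p * k];
      M[i + j * k] = s / Ljj;
    }
  }
  return true;
}

// solve L z = b then L' x = z (x overwrites b)
static void chol_solve(const std::vector<double>& L, int k, std::vector<double>& b) {
  for (int i = 0; i < k; ++i) {
    double s = b[i];
    for (int p = 0; p < i; ++p) s -= L[i + p * k] * b[p];
    b[i] = s / L[i + i * k];
  }
  for (int i = k - 1; i >= 0; --i) {
    double s = b[i];
    for (int p = i + 1; p < k; ++p) s -= L[p + i * k] * b[p];
    b[i] = s / L[i + i * k];
  }
}

// solve L' w = z only (w overwrites z)
static void backsolve_t(const std::vector<double>& L, int k, std::vector<double>& z) {
  for (int i = k - 1; i >= 0; --i) {
    double s = z[i];
    for (int p = i + 1; p < k; ++p) s -= L[p + i * k] * z[p];
    z[i] = s / L[i + i * k];
  }
}

// [[Rcpp::export(name = ".bayess_gibbs")]]
List bayess_gibbs(NumericMatrix X, NumericVector y, NumericMatrix Q,
                  NumericVector v2pq, int chain_length, int burn_in, int thin,
                  double s_prior_sd, double mh_step, double start_pi1,
                  double nu_b, double nu_e, double pi_a, double pi_b) {
  const int n = X.nrow(), m = X.ncol(), q = Q.ncol();
  const double* Xp = X.begin();
  const double* Qp = Q.begin();

  NumericVector xtx(m), logv(m);
  for (int j = 0; j < m; ++j) {
    const double* xj = Xp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
    logv[j] = std::log(v2pq[j]);
  }
  // center log v so S only tilts the slab variances across allele
  // frequencies; the overall scale belongs to sigma_b2 alone (removes the
  // S--sigma_b2 posterior ridge, which otherwise mixes poorly)
  double logv_bar = mean(logv);
  for (int j = 0; j < m; ++j) logv[j] -= logv_bar;
  NumericVector qtq(q);
  for (int k = 0; k < q; ++k) {
    const double* qk = Qp + (size_t)k * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += qk[i] * qk[i];
    qtq[k] = s;
  }

  double ybar = mean(y), vary = 0.0;
  for (int i = 0; i < n; ++i) vary += (y[i] - ybar) * (y[i] - ybar);
  vary /= (n - 1);

  // state
  NumericVector beta(m, 0.0), alpha(q, 0.0), qa(n, 0.0), r = clone(y);
  double S = 0.0, pi1 = start_pi1;
  double sigma_e2 = 0.5 * vary;
  double mean_v = mean(v2pq);
  double sigma_b2 = 0.5 * vary / std::max(1.0, start_pi1 * m * mean_v);
  double S2_b = sigma_b2, S2_e = 0.5 * vary;

  const int n_keep = (chain_length - burn_in + thin - 1) / thin;
  NumericVector keep_S(n_keep), keep_pi(n_keep), keep_h2(n_keep),
      keep_sb(n_keep), keep_se(n_keep);
  NumericVector pip(m, 0.0), beta_mean(m, 0.0);
  int kept = 0, n_accept = 0, n_prop = 0;

  RNGScope scope;
  for (int it = 0; it < chain_length; ++it) {
    // fixed effects, flat prior
    for (int k = 0; k < q; ++k) {
      const double* qk = Qp + (size_t)k * n;
      double old = alpha[k];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += qk[i] * (r[i] + qk[i] * old);
      double vpost = sigma_e2 / qtq[k];
      double anew = rhs / qtq[k] + std::sqrt(vpost) * norm_rand();
      double d = anew - old;
      alpha[k] = anew;
      for (int i = 0; i < n; ++i) { r[i] -= qk[i] * d; qa[i] += qk[i] * d; }
    }

    // SNP effects
    int m_in = 0;
    double ssb = 0.0;  // sum beta_j^2 / v_j^S over included
    double log_odds_base = std::log(pi1) - std::log1p(-pi1);
    double* rp = r.begin();
    for (int j = 0; j < m; ++j) {
      const double* xj = Xp + (size_t)j * n;
      double old = beta[j];
      if (old != 0.0)
        for (int i = 0; i < n; ++i) rp[i] += xj[i] * old;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * rp[i];
      double vj = std::exp(S * logv[j]) * sigma_b2;  // slab variance
      double v0 = xtx[j] * sigma_e2;                 // var(rhs | beta = 0)
      double v1 = v0 + xtx[j] * xtx[j] * vj;
      double logBF = 0.5 * (std::log(v0) - std::log(v1)) +
                     0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
      double lo = log_odds_base + logBF;
      double p_in = 1.0 / (1.0 + std::exp(-lo));
      double bnew = 0.0;
      if (unif_rand() < p_in) {
        double vpost = sigma_e2 / (xtx[j] + sigma_e2 / vj);
        double mpost = vpost * rhs / sigma_e2;
        bnew = mpost + std::sqrt(vpost) * norm_rand();
        ++m_in;
        ssb += bnew * bnew / std::exp(S * logv[j]);
      }
      beta[j] = bnew;
      if (bnew != 0.0)
        for (int i = 0; i < n; ++i) rp[i] -= xj[i] * bnew;
      if (it >= burn_in && bnew != 0.0) pip[j] += 1.0;
      if (it >= burn_in) beta_mean[j] += bnew;
    }

    // mixture weight (probability of a nonzero effect)
    pi1 = R::rbeta(pi_a + m_in, pi_b + (m - m_in));
    pi1 = std::min(std::max(pi1, 1e-6), 1.0 - 1e-6);

    // Partially collapsed S update: every s_every sweeps, sample S from its
    // conditional given the inclusion set with the included effects
    // integrated out (Woodbury on the k x k included block), then redraw
    // those effects jointly from their exact multivariate-normal
    // conditional. Conditioning S on the data rather than on the sampled
    // effects removes the feedback through weakly identified effects that
    // otherwise tilts S.
    const int s_every = 5, k_cap = 200;
    if (m_in > 0 && m_in <= k_cap && (it % s_every) == 0) {
      std::vector<int> idx;
      idx.reserve(m_in);
      for (int j = 0; j < m; ++j)
        if (beta[j] != 0.0) idx.push_back(j);
      const int k = (int)idx.size();
      std::vector<double> yt(n);
      double yty = 0.0;
      for (int i = 0; i < n; ++i) {
        yt[i] = y[i] - qa[i];
        yty += yt[i] * yt[i];
      }
      std::vector<double> G(k * k), bvec(k), lsub(k);
      for (int a = 0; a < k; ++a) {
        const double* xa = Xp + (size_t)idx[a] * n;
        lsub[a] = logv[idx[a]];
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += xa[i] * yt[i];
        bvec[a] = s;
        for (int c = a; c < k; ++c) {
          const double* xc = Xp + (size_t)idx[c] * n;
          double g = 0.0;
          for (int i = 0; i < n; ++i) g += xa[i] * xc[i];
          G[a + c * k] = G[c + a * k] = g;
        }
      }
      std::vector<double> M(k * k), u(k);
      // collapsed log-likelihood of S given the inclusion set
      auto loglik = [&](double Sv, bool keep_chol) -> double {
        std::copy(G.begin(), G.end(), M.begin());
        double logA = 0.0;
        for (int a = 0; a < k; ++a) {
          double Aj = sigma_b2 * std::exp(Sv * lsub[a]);
          logA += std::log(Aj);
          M[a + a * k] += sigma_e2 / Aj;
        }
        if (!chol_lower(M, k)) return -INFINITY;
        double logdet = 0.0;
        for (int a = 0; a < k; ++a) logdet += 2.0 * std::log(M[a + a * k]);
        std::copy(bvec.begin(), bvec.end(), u.begin());
        chol_solve(M, k, u);
        double quad = 0.0;
        for (int a = 0; a < k; ++a) quad += bvec[a] * u[a];
        (void)keep_chol;
        return -0.5 * (logA - k * std::log(sigma_e2) + logdet +
                       (yty - quad) / sigma_e2) -
               0.5 * Sv * Sv / (s_prior_sd * s_prior_sd);
      };
      double lcur = loglik(S, false);
      for (int t = 0; t < 10; ++t) {
        double Sp = S + mh_step * norm_rand();
        double lprop = loglik(Sp, false);
        ++n_prop;
        if (std::log(unif_rand()) < lprop - lcur) {
          S = Sp;
          lcur = lprop;
          ++n_accept;
        }
      }
      if (!std::isfinite(S)) stop("BayesS chain diverged: non-finite S");
      // joint redraw of the included effects given the accepted S
      // (M and u hold the factorization and mean for the last evaluated
      // proposal; recompute at the current S)
      lcur = loglik(S, true);
      std::vector<double> z(k);
      for (int a = 0; a < k; ++a) z[a] = norm_rand();
      backsolve_t(M, k, z);
      ssb = 0.0;
      double se = std::sqrt(sigma_e2);
      for (int a = 0; a < k; ++a) {
        double bnew = u[a] + se * z[a];
        beta[idx[a]] = bnew;
        ssb += bnew * bnew * std::exp(-S * lsub[a]);
      }
      // refresh the residual with the redrawn effects
      for (int i = 0; i < n; ++i) r[i] = yt[i];
      for (int a = 0; a < k; ++a) {
        const double* xa = Xp + (size_t)idx[a] * n;
        double bj = beta[idx[a]];
        for (int i = 0; i < n; ++i) r[i] -= xa[i] * bj;
      }
    } else if (m_in > 0) {
      // off-sweep (or oversized inclusion set): cheap update of S on the
      // slab prior of the current effects with sigma_b2 integrated out
      double Sp = S + mh_step * norm_rand();
      double sum_lv = 0.0, ssb_p = 0.0;
      ssb = 0.0;
      for (int j = 0; j < m; ++j) {
        if (beta[j] == 0.0) continue;
        double b2 = beta[j] * beta[j];
        sum_lv += logv[j];
        ssb += b2 * std::exp(-S * logv[j]);
        ssb_p += b2 * std::exp(-Sp * logv[j]);
      }
      double half_df = 0.5 * (nu_b + m_in);
      double lcur = -0.5 * S * S / (s_prior_sd * s_prior_sd) -
                    0.5 * S * sum_lv - half_df * std::log(nu_b * S2_b + ssb);
      double lprop = -0.5 * Sp * Sp / (s_prior_sd * s_prior_sd) -
                     0.5 * Sp * sum_lv - half_df * std::log(nu_b * S2_b + ssb_p);
      ++n_prop;
      if (std::log(unif_rand()) < lprop - lcur) {
        S = Sp;
        ssb = ssb_p;
        ++n_accept;
      }
      if (!std::isfinite(S)) stop("BayesS chain diverged: non-finite S");
    }

    // variances, scaled inverse chi-square conditionals
    sigma_b2 = (m_in > 0)
        ? (nu_b * S2_b + ssb) / R::rchisq(std::max(nu_b + m_in, 1.0))
        : (2.0 * S2_b) / R::rchisq(2.0);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += r[i] * r[i];
    sigma_e2 = (nu_e * S2_e + sse) / R::rchisq(nu_e + n);

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      // genetic values g = y - Q alpha - r
      double gs = 0.0, gss = 0.0;
      for (int i = 0; i < n; ++i) {
        double g = y[i] - qa[i] - r[i];
        gs += g; gss += g * g;
      }
      double varg = (gss - gs * gs / n) / (n - 1);
      keep_S[kept] = S;
      keep_pi[kept] = pi1;
      keep_h2[kept] = varg / (varg + sigma_e2);
      keep_sb[kept] = sigma_b2;
      keep_se[kept] = sigma_e2;
      ++kept;
      if (!std::isfinite(sse) || !std::isfinite(sigma_e2))
        stop("BayesS chain diverged: non-finite residual sum of squares");
    }
  }

  int denom = chain_length - burn_in;
  for (int j = 0; j < m; ++j) { pip[j] /= denom; beta_mean[j] /= denom; }

  return List::create(
      _["S"] = keep_S[Range(0, kept - 1)], _["pi"] = keep_pi[Range(0, kept - 1)],
      _["h2"] = keep_h2[Range(0, kept - 1)], _["sigma_b2"] = keep_sb[Range(0, kept - 1)],
      _["sigma_e2"] = keep_se[Range(0, kept - 1)], _["pip"] = pip,
      _["beta_mean"] = beta_mean,
      _["accept_rate"] = (double)n_accept / std::max(1, n_prop));
}
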