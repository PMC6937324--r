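// Blocked adaptive random-walk Metropolis-Hastings for the continuous-quality
// SOC model. Generic kinetics (u0, eta11) are proposed jointly against the
// pooled likelihood over all sites; each site's local parameters
// (q0, e0, beta0) are proposed jointly against that site's likelihood.
// Proposal covariances adapt (adaptive-Metropolis style) during burn-in only,
// so the post-burn-in kernel is a fixed Metropolis kernel. All randomness
// comes from R's RNG, so chains are reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct SiteData {
  std::vector<double> t_soc, y_soc;
  double sd_soc;
  std::vector<double> t_pf, y_pf;
  double sd_pf;
  double css, clay, re;
};

struct PriorRow {
  int dist; // 0 uniform, 1 truncated normal
  double mean, sd, lower, upper, log_z; // log_z: log truncation mass
};

// log prior density of a single parameter value
double log_prior_one(double x, const PriorRow& p) {
  if (x < p.lower || x > p.upper) return R_NegInf;
  if (p.dist == 0) return -std::log(p.upper - p.lower);
  return R::dnorm(x, p.mean, p.sd, 1) - p.log_z;
}

// structural validity of the parameter set restricted to one site
bool site_valid(double u0, double eta, double q0, double e0, double beta) {
  if (!(u0 > 0.0) || !(eta > 0.0) || !(q0 > 0.0)) return false;
  if (!(e0 > 0.0) || !(e0 < 1.0) || !(beta > 0.0)) return false;
  if ((1.0 - e0) / (eta * e0) - beta <= 0.0) return false;
  if (1.0 - e0 - eta * e0 * beta <= 0.0) return false;
  return true;
}

// Gaussian log likelihood and SOC RMSE for one site; returns false if the
// parameter set is invalid for this site.
bool site_fit(const std::vector<double>& par, int s,
              const std::vector<SiteData>& sites,
              const IntegerMatrix& local_idx,
              bool flat, int conv,
              double* loglik, double* rmse) {
  const SiteData& d = sites[s];
  const double u0 = par[0], eta = par[1];
  const double q0 = par[local_idx(s, 0)];
  const double e0 = par[local_idx(s, 1)];
  const double b0 = par[local_idx(s, 2)];
  const double beta = b0 + 0.01 * d.clay;
  if (!site_valid(u0, eta, q0, e0, beta)) return false;

  const double expnt = (1.0 - e0) / (eta * e0) - beta;
  const double q0b = std::pow(q0, beta);
  const double a = beta * eta * u0 * d.re * q0b;

  double ll = 0.0, sse = 0.0;
  const size_t n_soc = d.t_soc.size();
  for (size_t i = 0; i < n_soc; ++i) {
    const double ratio = std::exp(-std::log1p(a * d.t_soc[i]) / beta);
    const double pred = d.css * std::pow(ratio, expnt);
    const double res = d.y_soc[i] - pred;
    sse += res * res;
    if (!flat) ll += R::dnorm(d.y_soc[i], pred, d.sd_soc, 1);
  }
  if (!d.t_pf.empty()) {
    const double k = (conv == 0) ? u0 * d.re * q0b / e0
                                 : e0 / (u0 * d.re * q0b);
    if (!flat) {
      for (size_t i = 0; i < d.t_pf.size(); ++i) {
        const double pred = std::exp(-k * d.t_pf[i]);
        ll += R::dnorm(d.y_pf[i], pred, d.sd_pf, 1);
      }
    }
  }
  *loglik = ll;
  *rmse = n_soc > 0 ? std::sqrt(sse / n_soc) : NA_REAL;
  return true;
}

// Cholesky factor (lower) of a small SPD matrix; returns false on failure
bool chol_lower(const std::vector<double>& m, int d, std::vector<double>* l) {
  std::vector<double>& L = *l;
  L.assign(d * d, 0.0);
  for (int j = 0; j < d; ++j) {
    double diag = m[j * d + j];
    for (int k = 0; k < j; ++k) diag -= L[j * d + k] * L[j * d + k];
    if (diag <= 0.0) return false;
    L[j * d + j] = std::sqrt(diag);
    for (int i = j + 1; i < d; ++i) {
      double v = m[i * d + j];
      for (int k = 0; k < j; ++k) v -= L[i * d + k] * L[j * d + k];
      L[i * d + j] = v / L[j * d + j];
    }
  }
  return true;
}

} // namespace

// [[Rcpp::export]]
List qm_run_chain(NumericVector init,
                  List blocks_r,          // list of 0-based index vectors
                  IntegerVector block_site, // -1 pooled, else site index
                  NumericMatrix prior_spec, // dist, mean, sd, lower, upper, log_z
                  IntegerMatrix local_idx,  // n_sites x 3 (q0, e0, beta0)
                  List site_data,
                  List config) {
  const int n_iter = as<int>(config["n_iter"]);
  const int burn_in = as<int>(config["burn_in"]);
  const int thin = as<int>(config["thin"]);
  const double target = as<double>(config["target_accept"]);
  const bool flat = as<bool>(config["flat"]);
  const int conv = as<int>(config["conv"]);
  const int adapt_interval = as<int>(config["adapt_interval"]);

  const int n_par = init.size();
  const int n_sites = site_data.size();
  const int n_blocks = blocks_r.size();

  std::vector<SiteData> sites(n_sites);
  for (int s = 0; s < n_sites; ++s) {
    List d = site_data[s];
    sites[s].t_soc = as<std::vector<double>>(d["t_soc"]);
    sites[s].y_soc = as<std::vector<double>>(d["y_soc"]);
    sites[s].sd_soc = as<double>(d["sd_soc"]);
    sites[s].t_pf = as<std::vector<double>>(d["t_pf"]);
    sites[s].y_pf = as<std::vector<double>>(d["y_pf"]);
    sites[s].sd_pf = as<double>(d["sd_pf"]);
    sites[s].css = as<double>(d["css"]);
    sites[s].clay = as<double>(d["clay"]);
    sites[s].re = as<double>(d["re"]);
  }

  std::vector<PriorRow> priors(n_par);
  for (int j = 0; j < n_par; ++j) {
    priors[j].dist = (int) prior_spec(j, 0);
    priors[j].mean = prior_spec(j, 1);
    priors[j].sd = prior_spec(j, 2);
    priors[j].lower = prior_spec(j, 3);
    priors[j].upper = prior_spec(j, 4);
    priors[j].log_z = prior_spec(j, 5);
  }

  std::vector<std::vector<int>> blocks(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    blocks[b] = as<std::vector<int>>(blocks_r[b]);
  }

  // current state and cached per-site fit
  std::vector<double> cur(init.begin(), init.end());
  std::vector<double> cur_ll(n_sites), cur_rmse(n_sites);
  for (int s = 0; s < n_sites; ++s) {
    if (!site_fit(cur, s, sites, local_idx, flat, conv,
                  &cur_ll[s], &cur_rmse[s])) {
      stop("initial parameter set is invalid for site %d", s + 1);
    }
  }

  // adaptation state per block
  std::vector<double> log_lambda(n_blocks), base_scale;
  std::vector<std::vector<double>> mean_b(n_blocks), m2_b(n_blocks),
      chol_b(n_blocks);
  std::vector<long> count_b(n_blocks, 0);
  std::vector<long> prop_n(n_blocks, 0), acc_n(n_blocks, 0);
  std::vector<long> prop_post(n_blocks, 0), acc_post(n_blocks, 0);
  for (int b = 0; b < n_blocks; ++b) {
    const int d = blocks[b].size();
    log_lambda[b] = std::log(2.38 / std::sqrt((double) d));
    mean_b[b].assign(d, 0.0);
    m2_b[b].assign(d * d, 0.0);
    // start from a diagonal proposal scaled by the prior spread
    chol_b[b].assign(d * d, 0.0);
    for (int j = 0; j < d; ++j) {
      const PriorRow& p = priors[blocks[b][j]];
      double sc = (p.dist == 0) ? (p.upper - p.lower) / std::sqrt(12.0)
                                : p.sd;
      chol_b[b][j * d + j] = 0.3 * sc;
    }
  }

  const int n_keep = n_iter / thin;
  NumericMatrix draws(n_keep, n_par);
  NumericVector out_lp(n_keep), out_ll(n_keep), out_post(n_keep);
  IntegerVector out_iter(n_keep);
  NumericMatrix out_rmse(n_keep, n_sites);

  RNGScope scope;
  std::vector<double> prop(n_par), z, step;
  int keep = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    for (int b = 0; b < n_blocks; ++b) {
      const std::vector<int>& idx = blocks[b];
      const int d = idx.size();
      const double lambda = std::exp(log_lambda[b]);

      z.resize(d);
      for (int j = 0; j < d; ++j) z[j] = R::norm_rand();
      prop = cur;
      for (int i = 0; i < d; ++i) {
        double s = 0.0;
        for (int j = 0; j <= i; ++j) s += chol_b[b][i * d + j] * z[j];
        prop[idx[i]] = cur[idx[i]] + lambda * s;
      }

      // block prior difference
      double lp_new = 0.0, lp_old = 0.0;
      for (int j = 0; j < d; ++j) {
        lp_new += log_prior_one(prop[idx[j]], priors[idx[j]]);
        lp_old += log_prior_one(cur[idx[j]], priors[idx[j]]);
      }

      bool accepted = false;
      if (R_finite(lp_new)) {
        // affected sites
        double dll = 0.0;
        bool ok = true;
        std::vector<double> new_ll(n_sites), new_rmse(n_sites);
        if (block_site[b] < 0) {
          for (int s = 0; s < n_sites && ok; ++s) {
            ok = site_fit(prop, s, sites, local_idx, flat, conv,
                          &new_ll[s], &new_rmse[s]);
            if (ok) dll += new_ll[s] - cur_ll[s];
          }
        } else {
          const int s = block_site[b];
          ok = site_fit(prop, s, sites, local_idx, flat, conv,
                        &new_ll[s], &new_rmse[s]);
          if (ok) dll += new_ll[s] - cur_ll[s];
        }
        if (ok) {
          const double log_alpha = (lp_new - lp_old) + dll;
          if (std::log(R::unif_rand()) < log_alpha) {
            accepted = true;
            cur = prop;
            if (block_site[b] < 0) {
              for (int s = 0; s < n_sites; ++s) {
                cur_ll[s] = new_ll[s];
                cur_rmse[s] = new_rmse[s];
              }
            } else {
              cur_ll[block_site[b]] = new_ll[block_site[b]];
              cur_rmse[block_site[b]] = new_rmse[block_site[b]];
            }
          }
        }
      }

      ++prop_n[b];
      if (accepted) ++acc_n[b];
      if (iter > burn_in) {
        ++prop_post[b];
        if (accepted) ++acc_post[b];
      }

      if (iter <= burn_in) {
        // Robbins-Monro scale adaptation towards the target acceptance
        const double gamma = 1.0 / std::pow((double) prop_n[b], 0.6);
        log_lambda[b] += gamma * ((accepted ? 1.0 : 0.0) - target);
        // drop the initial transient from the covariance estimate
        if (iter == burn_in / 2) {
          count_b[b] = 0;
          std::fill(mean_b[b].begin(), mean_b[b].end(), 0.0);
          std::fill(m2_b[b].begin(), m2_b[b].end(), 0.0);
        }
        // Welford update of the block sample covariance
        ++count_b[b];
        std::vector<double> delta(d);
        for (int j = 0; j < d; ++j) {
          delta[j] = cur[idx[j]] - mean_b[b][j];
          mean_b[b][j] += delta[j] / count_b[b];
        }
        for (int i = 0; i < d; ++i) {
          for (int j = 0; j < d; ++j) {
            m2_b[b][i * d + j] +=
                delta[i] * (cur[idx[j]] - mean_b[b][j]);
          }
        }
        if (count_b[b] >= 200 && count_b[b] % adapt_interval == 0) {
          std::vector<double> cov(d * d);
          for (int i = 0; i < d * d; ++i) {
            cov[i] = m2_b[b][i] / (count_b[b] - 1);
          }
          for (int j = 0; j < d; ++j) cov[j * d + j] += 1e-12;
          std::vector<double> L;
          if (chol_lower(cov, d, &L)) chol_b[b] = L;
        }
      }
    }

    if (iter % thin == 0) {
      double lp = 0.0;
      for (int j = 0; j < n_par; ++j) lp += log_prior_one(cur[j], priors[j]);
      double ll = 0.0;
      for (int s = 0; s < n_sites; ++s) ll += cur_ll[s];
      for (int j = 0; j < n_par; ++j) draws(keep, j) = cur[j];
      for (int s = 0; s < n_sites; ++s) out_rmse(keep, s) = cur_rmse[s];
      out_lp[keep] = lp;
      out_ll[keep] = ll;
      out_post[keep] = lp + ll;
      out_iter[keep] = iter;
      ++keep;
    }
  }

  NumericVector acc_rate(n_blocks), acc_rate_post(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    acc_rate[b] = prop_n[b] > 0 ? (double) acc_n[b] / prop_n[b] : NA_REAL;
    acc_rate_post[b] = prop_post[b] > 0
        ? (double) acc_post[b] / prop_post[b] : NA_REAL;
  }

  return List::create(
      _["draws"] = draws, _["iteration"] = out_iter,
      _["log_prior"] = out_lp, _["log_lik"] = out_ll,
      _["log_post"] = out_post, _["rmse"] = out_rmse,
      _["accept_rate"] = acc_rate, _["accept_rate_post"] = acc_rate_post);
}
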