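#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the multiple-variance Brownian
// motion model:
//   x_child | x_parent ~ N(x_parent, sigma2 * r_b * t_b)  per branch b
//   ln r_b ~ N(0, nu^2) iid,  sigma2 ~ inverse-gamma(shape, rate),
//   root state flat.
// Internal node states and sigma2 have conjugate full conditionals
// (Gibbs); ln r_b is updated by random-walk Metropolis. Tip states are
// data and never touched. nu <= 0 pins every multiplier at 1 (plain BM).
// All draws come from R's RNG so a set.seed() in R fixes the whole chain.

// [[Rcpp::export]]
List mvbm_mcmc_cpp(IntegerMatrix edge, NumericVector edge_length,
                   int n_tip, NumericVector init_states,
                   int iterations, int burnin, int thin,
                   double nu, double prior_shape, double prior_rate,
                   double proposal_sd, double init_sigma2) {
  const int m = edge.nrow();            // branches
  const int ntot = init_states.size();  // nodes, ape numbering (1-based ids)
  const int root = n_tip;               // 0-based index of node n_tip + 1

  std::vector<double> x(init_states.begin(), init_states.end());
  std::vector<double> lnr(m, 0.0);
  double sigma2 = init_sigma2;

  // incidence lists: for each node, the edges touching it
  std::vector< std::vector<int> > inc(ntot);
  std::vector<int> par(ntot, -1), child(m), parent(m);
  for (int b = 0; b < m; ++b) {
    parent[b] = edge(b, 0) - 1;
    child[b]  = edge(b, 1) - 1;
    inc[parent[b]].push_back(b);
    inc[child[b]].push_back(b);
    par[child[b]] = parent[b];
  }
  std::vector<int> internal_nodes;
  for (int i = n_tip; i < ntot; ++i) internal_nodes.push_back(i);

  const bool update_rates = nu > 0.0;
  const int n_keep = (iterations - burnin) / thin;
  NumericMatrix states_out(n_keep, ntot);
  NumericMatrix lnr_out(n_keep, m);
  NumericVector sigma2_out(n_keep);
  NumericVector log_joint_out(n_keep);
  std::vector<double> accept(m, 0.0);
  int kept = 0;

  for (int it = 1; it <= iterations; ++it) {
    // --- Gibbs: internal node states ---
    for (size_t k = 0; k < internal_nodes.size(); ++k) {
      int i = internal_nodes[k];
      double prec = 0.0, wsum = 0.0;
      for (size_t e = 0; e < inc[i].size(); ++e) {
        int b = inc[i][e];
        double w = sigma2 * std::exp(lnr[b]) * edge_length[b];
        int nb = (child[b] == i) ? parent[b] : child[b];
        prec += 1.0 / w;
        wsum += x[nb] / w;
      }
      double mu = wsum / prec;
      x[i] = mu + std::sqrt(1.0 / prec) * norm_rand();
    }

    // --- Gibbs: sigma2 | increments (conjugate inverse-gamma) ---
    double ssq = 0.0;
    for (int b = 0; b < m; ++b) {
      double d = x[child[b]] - x[parent[b]];
      ssq += d * d / (std::exp(lnr[b]) * edge_length[b]);
    }
    double shape = prior_shape + 0.5 * m;
    double rate  = prior_rate + 0.5 * ssq;
    sigma2 = rate / R::rgamma(shape, 1.0); // 1/Gamma(shape, 1/rate)

    // --- Metropolis: ln r_b per branch ---
    if (update_rates) {
      for (int b = 0; b < m; ++b) {
        double d = x[child[b]] - x[parent[b]];
        double st = sigma2 * edge_length[b];
        double cur = lnr[b];
        double prop = cur + proposal_sd * norm_rand();
        // log target: N(ln r; 0, nu^2) prior + N(d; 0, sigma2 r t) increment
        double lp_cur  = -0.5 * cur * cur / (nu * nu) - 0.5 * cur
                         - 0.5 * d * d / (st * std::exp(cur));
        double lp_prop = -0.5 * prop * prop / (nu * nu) - 0.5 * prop
                         - 0.5 * d * d / (st * std::exp(prop));
        if (std::log(unif_rand()) < lp_prop - lp_cur) {
          lnr[b] = prop;
          if (it > burnin) accept[b] += 1.0;
        }
      }
    }

    if (it > burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      double lj = 0.0;
      for (int b = 0; b < m; ++b) {
        double d = x[child[b]] - x[parent[b]];
        double v = sigma2 * std::exp(lnr[b]) * edge_length[b];
        lj += -0.5 * (std::log(2.0 * M_PI * v) + d * d / v);
        if (update_rates)
          lj += -0.5 * lnr[b] * lnr[b] / (nu * nu);
      }
      lj += -(prior_shape + 1.0) * std::log(sigma2) - prior_rate / sigma2;
      for (int j = 0; j < ntot; ++j) states_out(kept, j) = x[j];
      for (int b = 0; b < m; ++b) lnr_out(kept, b) = lnr[b];
      sigma2_out[kept] = sigma2;
      log_joint_out[kept] = lj;
      ++kept;
    }
  }

  int post_iter = iterations - burnin;
  NumericVector accept_frac(m);
  for (int b = 0; b < m; ++b)
    accept_frac[b] = update_rates ? accept[b] / post_iter : NA_REAL;

  (void)root;
  return List::create(
    _["states"] = states_out,
    _["lnr"] = lnr_out,
    _["sigma2"] = sigma2_out,
    _["log_joint"] = log_joint_out,
    _["accept_frac"] = accept_frac,
    _["n_kept"] = kept);
}
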