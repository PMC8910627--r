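// Gibbs kernels for the Dirichlet-process mixture of polynomial growth curves.
//
// Model: y_ij = alpha + x(t_ij)' beta + z(t_ij)' b_i + eps_ij,
//   eps_ij ~ N(0, 1/tau_eps),  b_i ~ F,  F ~ DP(c, F0),
//   F0 = N(0, diag(tau_b)^-1),  tau_* ~ Gamma(shape, rate),  c ~ Gamma(a, 1).
// Random-effect vectors are instantiated (Neal's Algorithm 2): label updates
// use the closed-form marginal likelihood for a fresh cluster, everything
// else is conjugate Gaussian/Gamma. All randomness comes from R's RNG so
// set.seed() in R makes runs bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct PanelData {
  std::vector<arma::vec> y;  // observed cells per series
  std::vector<arma::mat> X;  // fixed basis rows (u, u^2, ..., u^n)
  std::vector<arma::mat> Z;  // random basis rows (1, u, ..., u^n)
  int n = 0;                 // number of series
  int p = 0;                 // fixed-effect dimension (degree)
  int q = 0;                 // random-effect dimension (degree + 1)
  int n_obs = 0;
};

PanelData unpack_data(const List& data) {
  PanelData d;
  List ly = data["y"], lX = data["X"], lZ = data["Z"];
  d.n = ly.size();
  for (int i = 0; i < d.n; ++i) {
    d.y.push_back(as<arma::vec>(ly[i]));
    d.X.push_back(as<arma::mat>(lX[i]));
    d.Z.push_back(as<arma::mat>(lZ[i]));
    d.n_obs += d.y[i].n_elem;
  }
  d.p = d.X[0].n_cols;
  d.q = d.Z[0].n_cols;
  return d;
}

struct State {
  double alpha;
  arma::vec beta;       // length p
  arma::ivec z;         // 0-based labels, length n
  arma::mat phi;        // K x q cluster random-effect vectors
  arma::vec tau_b;      // length q
  double tau_eps;
  double conc;          // DP concentration c
};

State unpack_state(const List& st) {
  State s;
  s.alpha = as<double>(st["alpha"]);
  s.beta = as<arma::vec>(st["beta"]);
  s.z = as<arma::ivec>(st["z"]) - 1;  // R side is 1-based
  s.phi = as<arma::mat>(st["phi"]);
  s.tau_b = as<arma::vec>(st["tau_b"]);
  s.tau_eps = as<double>(st["tau_eps"]);
  s.conc = as<double>(st["c"]);
  return s;
}

List pack_state(const State& s) {
  IntegerVector z1(s.z.begin(), s.z.end());
  for (int& v : z1) v += 1;
  return List::create(
      _["alpha"] = s.alpha,
      _["beta"] = NumericVector(s.beta.begin(), s.beta.end()),
      _["z"] = z1, _["phi"] = s.phi,
      _["tau_b"] = NumericVector(s.tau_b.begin(), s.tau_b.end()),
      _["tau_eps"] = s.tau_eps, _["c"] = s.conc);
}

double log2pi() { return std::log(2.0 * M_PI); }

// log N(r | Z phi, I/tau_eps)
double loglik_cluster(const arma::vec& r, const arma::mat& Z,
                      const arma::vec& phi, double tau_eps) {
  arma::vec e = r - Z * phi;
  double M = r.n_elem;
  return 0.5 * M * (std::log(tau_eps) - log2pi()) -
         0.5 * tau_eps * arma::dot(e, e);
}

// log integral N(r | Z phi, I/tau_eps) dN(phi | 0, diag(tau_b)^-1);
// also returns the conditional posterior precision A and linear term b
double log_marginal(const arma::vec& r, const arma::mat& Z, double tau_eps,
                    const arma::vec& tau_b, arma::mat& A, arma::vec& b) {
  double M = r.n_elem;
  A = arma::diagmat(tau_b) + tau_eps * (Z.t() * Z);
  b = tau_eps * (Z.t() * r);
  double ld, sign;
  arma::log_det(ld, sign, A);
  arma::vec m = arma::solve(A, b, arma::solve_opts::likely_sympd);
  return 0.5 * M * (std::log(tau_eps) - log2pi()) +
         0.5 * arma::accu(arma::log(tau_b)) - 0.5 * ld -
         0.5 * tau_eps * arma::dot(r, r) + 0.5 * arma::dot(b, m);
}

// draw from N(A^-1 b, A^-1) via the Cholesky factor of the precision
arma::vec draw_gaussian_precision(const arma::mat& A, const arma::vec& b) {
  arma::mat R;
  if (!arma::chol(R, A))
    stop("singular conditional precision in Gaussian update");
  arma::vec mu = arma::solve(A, b, arma::solve_opts::likely_sympd);
  arma::vec zdraw(b.n_elem);
  for (arma::uword j = 0; j < zdraw.n_elem; ++j) zdraw[j] = R::norm_rand();
  return mu + arma::solve(arma::trimatu(R), zdraw);
}

int sample_log_weights(const arma::vec& logw) {
  if (!logw.is_finite())
    stop("non-finite cluster-assignment weight (degenerate precisions?)");
  arma::vec w = arma::exp(logw - logw.max());
  w /= arma::accu(w);
  double u = R::unif_rand(), acc = 0.0;
  for (arma::uword k = 0; k < w.n_elem; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return w.n_elem - 1;
}

// relabel clusters in order of first appearance in z; reorder phi rows
void canonicalize(State& s) {
  int K = s.phi.n_rows;
  arma::ivec newlab(K);
  newlab.fill(-1);
  arma::mat phi_new(K, s.phi.n_cols);
  int next = 0;
  for (arma::uword i = 0; i < s.z.n_elem; ++i) {
    int k = s.z[i];
    if (newlab[k] < 0) {
      newlab[k] = next;
      phi_new.row(next) = s.phi.row(k);
      ++next;
    }
  }
  for (arma::uword i = 0; i < s.z.n_elem; ++i) s.z[i] = newlab[s.z[i]];
  s.phi = phi_new;
}

void residuals_fixed(const PanelData& d, const State& s,
                     std::vector<arma::vec>& r) {
  r.resize(d.n);
  for (int i = 0; i < d.n; ++i)
    r[i] = d.y[i] - s.alpha - d.X[i] * s.beta;
}

void kernel_assignments(State& s, const PanelData& d) {
  std::vector<arma::vec> r;
  residuals_fixed(d, s, r);
  int K = s.phi.n_rows;
  arma::ivec counts(K, arma::fill::zeros);
  for (int i = 0; i < d.n; ++i) counts[s.z[i]]++;

  for (int i = 0; i < d.n; ++i) {
    int k_old = s.z[i];
    counts[k_old]--;
    if (counts[k_old] == 0) {  // prune the now-empty cluster
      s.phi.shed_row(k_old);
      counts.shed_row(k_old);
      K--;
      for (int j = 0; j < d.n; ++j)
        if (s.z[j] > k_old) s.z[j]--;
      s.z[i] = -1;
    }
    arma::vec logw(K + 1);
    for (int k = 0; k < K; ++k)
      logw[k] = std::log((double)counts[k]) +
                loglik_cluster(r[i], d.Z[i], s.phi.row(k).t(), s.tau_eps);
    arma::mat A;
    arma::vec b;
    logw[K] = std::log(s.conc) +
              log_marginal(r[i], d.Z[i], s.tau_eps, s.tau_b, A, b);
    int pick = sample_log_weights(logw);
    if (pick == K) {  // open a new cluster, draw its effect from the posterior
      s.phi.insert_rows(K, draw_gaussian_precision(A, b).t());
      counts.insert_rows(K, arma::ivec{1});
      K++;
    } else {
      counts[pick]++;
    }
    s.z[i] = pick;
  }
  canonicalize(s);
}

void kernel_cluster_effects(State& s, const PanelData& d) {
  std::vector<arma::vec> r;
  residuals_fixed(d, s, r);
  int K = s.phi.n_rows;
  for (int k = 0; k < K; ++k) {
    arma::mat A = arma::diagmat(s.tau_b);
    arma::vec b(d.q, arma::fill::zeros);
    for (int i = 0; i < d.n; ++i) {
      if (s.z[i] != k) continue;
      A += s.tau_eps * (d.Z[i].t() * d.Z[i]);
      b += s.tau_eps * (d.Z[i].t() * r[i]);
    }
    s.phi.row(k) = draw_gaussian_precision(A, b).t();
  }
}

void kernel_fixed_effects(State& s, const PanelData& d, double prior_sd) {
  int pp = d.p + 1;  // (alpha, beta)
  arma::mat A = arma::eye(pp, pp) / (prior_sd * prior_sd);
  arma::vec b(pp, arma::fill::zeros);
  for (int i = 0; i < d.n; ++i) {
    arma::mat W(d.y[i].n_elem, pp);
    W.col(0).ones();
    W.cols(1, pp - 1) = d.X[i];
    arma::vec si = d.y[i] - d.Z[i] * s.phi.row(s.z[i]).t();
    A += s.tau_eps * (W.t() * W);
    b += s.tau_eps * (W.t() * si);
  }
  arma::vec ab = draw_gaussian_precision(A, b);
  s.alpha = ab[0];
  s.beta = ab.subvec(1, pp - 1);
}

void kernel_precisions(State& s, const PanelData& d, double shape,
                       double rate, bool shared_tau_b) {
  double ssr = 0.0;
  for (int i = 0; i < d.n; ++i) {
    arma::vec e = d.y[i] - s.alpha - d.X[i] * s.beta -
                  d.Z[i] * s.phi.row(s.z[i]).t();
    ssr += arma::dot(e, e);
  }
  s.tau_eps = R::rgamma(shape + 0.5 * d.n_obs, 1.0 / (rate + 0.5 * ssr));
  int K = s.phi.n_rows;
  if (shared_tau_b) {  // isotropic base measure N(0, tau^-1 I): one tau
    double ss = arma::accu(arma::square(s.phi));
    s.tau_b.fill(R::rgamma(shape + 0.5 * K * d.q, 1.0 / (rate + 0.5 * ss)));
  } else {
    for (int dd = 0; dd < d.q; ++dd) {
      double ss = arma::dot(s.phi.col(dd), s.phi.col(dd));
      s.tau_b[dd] = R::rgamma(shape + 0.5 * K, 1.0 / (rate + 0.5 * ss));
    }
  }
}

// Escobar & West auxiliary-variable update for the DP concentration,
// prior c ~ Gamma(a, 1)
void kernel_concentration(State& s, int n, double a) {
  int K = s.phi.n_rows;
  double eta = R::rbeta(s.conc + 1.0, (double)n);
  double rate = 1.0 - std::log(eta);
  double odds = (a + K - 1.0) / ((double)n * rate);
  if (R::unif_rand() < odds / (1.0 + odds))
    s.conc = R::rgamma(a + K, 1.0 / rate);
  else
    s.conc = R::rgamma(a + K - 1.0, 1.0 / rate);
}

double full_loglik(const State& s, const PanelData& d) {
  double ll = 0.0;
  for (int i = 0; i < d.n; ++i) {
    arma::vec r = d.y[i] - s.alpha - d.X[i] * s.beta;
    ll += loglik_cluster(r, d.Z[i], s.phi.row(s.z[i]).t(), s.tau_eps);
  }
  return ll;
}

}  // namespace

// [[Rcpp::export]]
List cpp_update_assignments(List state, List data) {
  PanelData d = unpack_data(data);
  State s = unpack_state(state);
  kernel_assignments(s, d);
  return pack_state(s);
}

// [[Rcpp::export]]
List cpp_update_cluster_effects(List state, List data) {
  PanelData d = unpack_data(data);
  State s = unpack_state(state);
  kernel_cluster_effects(s, d);
  return pack_state(s);
}

// [[Rcpp::export]]
List cpp_update_fixed_effects(List state, List data, double prior_sd_fixed) {
  PanelData d = unpack_data(data);
  State s = unpack_state(state);
  kernel_fixed_effects(s, d, prior_sd_fixed);
  return pack_state(s);
}

// [[Rcpp::export]]
List cpp_update_precisions(List state, List data, double gamma_shape,
                           double gamma_rate, bool shared_tau_b) {
  PanelData d = unpack_data(data);
  State s = unpack_state(state);
  kernel_precisions(s, d, gamma_shape, gamma_rate, shared_tau_b);
  return pack_state(s);
}

// [[Rcpp::export]]
List cpp_update_concentration(List state, int n_countries, double a) {
  State s = unpack_state(state);
  kernel_concentration(s, n_countries, a);
  return pack_state(s);
}

// [[Rcpp::export]]
double cpp_log_likelihood(List state, List data) {
  PanelData d = unpack_data(data);
  State s = unpack_state(state);
  return full_loglik(s, d);
}

// [[Rcpp::export]]
double cpp_log_marginal(NumericVector r, NumericMatrix Z, double tau_eps,
                        NumericVector tau_b) {
  arma::mat A;
  arma::vec b;
  return log_marginal(as<arma::vec>(r), as<arma::mat>(Z), tau_eps,
                      as<arma::vec>(tau_b), A, b);
}

// [[Rcpp::export]]
List cpp_run_mcmc(List data, List init, int n_iter, int burn_in, int thin,
                  double a, double gamma_shape, double gamma_rate,
                  double prior_sd_fixed, bool shared_tau_b) {
  PanelData d = unpack_data(data);
  State s = unpack_state(init);
  int n_keep = (n_iter - burn_in) / thin;
  arma::vec alpha_dr(n_keep), tau_eps_dr(n_keep), c_dr(n_keep), ll_dr(n_keep);
  arma::mat beta_dr(n_keep, d.p), tau_b_dr(n_keep, d.q);
  arma::imat z_dr(n_keep, d.n), K_dr(n_keep, 1);
  arma::cube b_dr(d.n, d.q, n_keep);  // per-series random-effect vectors

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    kernel_assignments(s, d);
    kernel_cluster_effects(s, d);
    kernel_fixed_effects(s, d, prior_sd_fixed);
    kernel_precisions(s, d, gamma_shape, gamma_rate, shared_tau_b);
    kernel_concentration(s, d.n, a);
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      double ll = full_loglik(s, d);
      if (!std::isfinite(ll))
        stop("non-finite log-likelihood at iteration %d", it);
      alpha_dr[kept] = s.alpha;
      beta_dr.row(kept) = s.beta.t();
      tau_eps_dr[kept] = s.tau_eps;
      tau_b_dr.row(kept) = s.tau_b.t();
      c_dr[kept] = s.conc;
      ll_dr[kept] = ll;
      K_dr(kept, 0) = s.phi.n_rows;
      for (int i = 0; i < d.n; ++i) {
        z_dr(kept, i) = s.z[i] + 1;
        b_dr.slice(kept).row(i) = s.phi.row(s.z[i]);
      }
      ++kept;
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["alpha"] = alpha_dr, _["beta"] = beta_dr, _["z"] = z_dr,
      _["b"] = b_dr, _["tau_b"] = tau_b_dr, _["tau_eps"] = tau_eps_dr,
      _["c"] = c_dr, _["K"] = K_dr.col(0), _["loglik"] = ll_dr,
      _["final_state"] = pack_state(s));
}
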