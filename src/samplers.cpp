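#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Spike-and-slab Gibbs machinery shared by the SAME sampler and the
// fixed-parameter weight generator. Effects are kept on the
// standardized scale b_m = beta_m / s_m, for which z | b ~ N(R b, R)
// per block. Off-diagonal structure is precompiled into neighbor lists
// so sweeps cost O(M * bandwidth).

struct BlockGraph {
  std::vector<int> snp;                    // global 0-based SNP index
  std::vector<std::vector<int> > nb;      // neighbor global indices
  std::vector<std::vector<double> > w;    // corresponding R entries
};

static std::vector<BlockGraph> build_graph(const List& block_idx,
                                           const List& block_R) {
  int nb = block_idx.size();
  std::vector<BlockGraph> g(nb);
  for (int k = 0; k < nb; ++k) {
    IntegerVector idx = block_idx[k];
    NumericMatrix R = block_R[k];
    int p = idx.size();
    g[k].snp.resize(p);
    g[k].nb.resize(p);
    g[k].w.resize(p);
    for (int a = 0; a < p; ++a) {
      g[k].snp[a] = idx[a] - 1;  // to 0-based
      for (int b = 0; b < p; ++b) {
        if (b == a) continue;
        double r = R(a, b);
        if (r != 0.0) {
          g[k].nb[a].push_back(idx[b] - 1);
          g[k].w[a].push_back(r);
        }
      }
    }
  }
  return g;
}

// one Gibbs sweep over all SNPs of all blocks for one replicate state
static void sweep_once(const std::vector<BlockGraph>& graph,
                       const NumericVector& z, double pi, double sigma2,
                       std::vector<double>& b, std::vector<int>& gam) {
  double lambda = 1.0 / (1.0 + 1.0 / sigma2);
  double log_pi = std::log(pi), log_1mpi = std::log1p(-pi);
  double log_pref = 0.5 * std::log(lambda) - 0.5 * std::log(sigma2);
  for (size_t k = 0; k < graph.size(); ++k) {
    const BlockGraph& G = graph[k];
    for (size_t a = 0; a < G.snp.size(); ++a) {
      int m = G.snp[a];
      double resid = 0.0;
      for (size_t j = 0; j < G.nb[a].size(); ++j)
        resid += G.w[a][j] * b[G.nb[a][j]];
      double mu = lambda * (z[m] - resid);
      // spike-vs-slab odds with b_m marginalized out, in log domain:
      // r = pi*sqrt(lambda)/sigma * exp(mu^2 / (2 lambda))
      double log_r = log_pi + log_pref + mu * mu / (2.0 * lambda);
      double t = log_1mpi - log_r;
      double h = (t > 35.0) ? 0.0 : ((t < -35.0) ? 1.0 : 1.0 / (1.0 + std::exp(t)));
      gam[m] = (R::unif_rand() < h) ? 1 : 0;
      // b_m refreshed from its conditional given the new indicator, so
      // the state always satisfies b_m = 0 wherever gamma_m = 0
      b[m] = (gam[m] == 1) ? R::rnorm(mu, std::sqrt(lambda)) : 0.0;
    }
  }
}

// delta = S R b computed blockwise (natural allele-frequency scale)
static void delta_from_b(const std::vector<BlockGraph>& graph,
                         const NumericVector& s,
                         const std::vector<double>& b,
                         std::vector<double>& delta) {
  for (size_t k = 0; k < graph.size(); ++k) {
    const BlockGraph& G = graph[k];
    for (size_t a = 0; a < G.snp.size(); ++a) {
      int m = G.snp[a];
      double acc = b[m];
      for (size_t j = 0; j < G.nb[a].size(); ++j)
        acc += G.w[a][j] * b[G.nb[a][j]];
      delta[m] = s[m] * acc;
    }
  }
}

// [[Rcpp::export(name = ".same_gibbs_cpp")]]
List same_gibbs_cpp(NumericVector z, NumericVector s, List block_idx,
                    List block_R, double pi0, double sigma2_0, int d_max,
                    int window, double tol, int n_auc_draws,
                    NumericMatrix omega, NumericVector auc_denom) {
  int M = z.size();
  int K = omega.ncol();
  std::vector<BlockGraph> graph = build_graph(block_idx, block_R);

  const double pi_lo = 1e-12, pi_hi = 1.0 - 1e-12, sig_lo = 1e-12;
  double pi = std::min(std::max(pi0, pi_lo), pi_hi);
  double sigma2 = std::max(sigma2_0, sig_lo);

  std::vector<std::vector<double> > b;
  std::vector<std::vector<int> > gam;
  auto new_replicate = [&]() {
    std::vector<double> bi(M, 0.0);
    std::vector<int> gi(M, 0);
    for (int m = 0; m < M; ++m) {
      gi[m] = (R::unif_rand() < pi) ? 1 : 0;
      if (gi[m]) bi[m] = R::rnorm(0.0, std::sqrt(sigma2));
    }
    b.push_back(bi);
    gam.push_back(gi);
  };
  new_replicate();  // D = 1

  std::vector<double> pi_trace, sig_trace;
  bool converged = false;
  int outer = 0;
  while ((int)b.size() <= d_max) {
    ++outer;
    int D = b.size();
    for (int d = 0; d < D; ++d) sweep_once(graph, z, pi, sigma2, b[d], gam[d]);
    // conjugate pooled updates across replicates
    double sum_g = 0.0, sum_b2g = 0.0;
    for (int d = 0; d < D; ++d)
      for (int m = 0; m < M; ++m)
        if (gam[d][m]) { sum_g += 1.0; sum_b2g += b[d][m] * b[d][m]; }
    pi = R::rbeta(sum_g + D, (double)M * D - sum_g + D);
    pi = std::min(std::max(pi, pi_lo), pi_hi);
    if (sum_b2g > 0.0) {
      double prec = R::rgamma(0.5 * sum_g + D, 1.0 / (0.5 * sum_b2g));
      sigma2 = std::max(1.0 / prec, sig_lo);
    }
    pi_trace.push_back(pi);
    sig_trace.push_back(sigma2);

    int t = pi_trace.size();
    if (t >= 2 * window) {
      double p1 = 0, p2 = 0, s1 = 0, s2 = 0;
      for (int i = t - window; i < t; ++i) { p1 += pi_trace[i]; s1 += sig_trace[i]; }
      for (int i = t - 2 * window; i < t - window; ++i) { p2 += pi_trace[i]; s2 += sig_trace[i]; }
      p1 /= window; p2 /= window; s1 /= window; s2 /= window;
      double dp = std::fabs(p1 - p2) / std::max(std::fabs(p2), 1e-12);
      double ds = std::fabs(s1 - s2) / std::max(std::fabs(s2), 1e-12);
      if (dp < tol && ds < tol) { converged = true; break; }
    }
    if ((int)b.size() == d_max) break;
    new_replicate();  // D <- D + 1, existing replicates warm-started
  }

  // freeze (pi, sigma2) at running means of the last window
  int t = pi_trace.size();
  int w = std::min(window, t);
  double pi_hat = 0, sig_hat = 0;
  for (int i = t - w; i < t; ++i) { pi_hat += pi_trace[i]; sig_hat += sig_trace[i]; }
  pi_hat /= w; sig_hat /= w;
  pi_hat = std::min(std::max(pi_hat, pi_lo), pi_hi);
  sig_hat = std::max(sig_hat, sig_lo);

  // post-convergence sweeps of the last replicate collect delta and AUC
  NumericMatrix auc_draws(n_auc_draws, K);
  NumericVector delta_mean(M);
  std::vector<double>& bf = b.back();
  std::vector<int>& gf = gam.back();
  std::vector<double> delta(M, 0.0);
  for (int it = 0; it < n_auc_draws; ++it) {
    sweep_once(graph, z, pi_hat, sig_hat, bf, gf);
    delta_from_b(graph, s, bf, delta);
    for (int m = 0; m < M; ++m) delta_mean[m] += delta[m] / n_auc_draws;
    for (int k = 0; k < K; ++k) {
      double num = 0.0;
      for (int m = 0; m < M; ++m) num += omega(m, k) * delta[m];
      auc_draws(it, k) = (auc_denom[k] > 0.0)
        ? R::pnorm(2.0 * num / auc_denom[k], 0.0, 1.0, 1, 0) : 0.5;
    }
  }

  return List::create(
    _["pi_hat"] = pi_hat, _["sigma_sq_hat"] = sig_hat,
    _["pi_trace"] = NumericVector(pi_trace.begin(), pi_trace.end()),
    _["sigma_sq_trace"] = NumericVector(sig_trace.begin(), sig_trace.end()),
    _["D"] = (int)b.size(), _["n_outer"] = outer,
    _["converged"] = converged, _["auc_draws"] = auc_draws,
    _["delta_mean"] = delta_mean,
    _["beta_final"] = NumericVector(bf.begin(), bf.end()),
    _["gamma_final"] = IntegerVector(gf.begin(), gf.end()));
}

// [[Rcpp::export(name = ".gibbs_fixed_cpp")]]
List gibbs_fixed_cpp(NumericVector z, NumericVector s, List block_idx,
                     List block_R, double pi, double sigma2, int n_iter,
                     int burn_in) {
  int M = z.size();
  std::vector<BlockGraph> graph = build_graph(block_idx, block_R);
  std::vector<double> b(M, 0.0);
  std::vector<int> gam(M, 0);
  for (int m = 0; m < M; ++m) {
    gam[m] = (R::unif_rand() < pi) ? 1 : 0;
    if (gam[m]) b[m] = R::rnorm(0.0, std::sqrt(sigma2));
  }
  std::vector<double> delta(M, 0.0);
  NumericVector delta_mean(M), b_mean(M), gamma_mean(M);
  // exhaustive gamma-configuration counts, feasible for tiny M only
  bool track_cfg = (M <= 16);
  IntegerVector cfg_counts(track_cfg ? (1 << M) : 0);
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    sweep_once(graph, z, pi, sigma2, b, gam);
    for (int m = 0; m < M; ++m)
      if (!std::isfinite(b[m]))
        stop("spike-slab sampler diverged (non-finite effect); use a smaller slab scale");
    if (it >= burn_in) {
      ++kept;
      delta_from_b(graph, s, b, delta);
      for (int m = 0; m < M; ++m) {
        delta_mean[m] += delta[m];
        b_mean[m] += b[m];
        gamma_mean[m] += gam[m];
      }
      if (track_cfg) {
        int code = 0;
        for (int m = 0; m < M; ++m) if (gam[m]) code |= (1 << m);
        ++cfg_counts[code];
      }
    }
  }
  if (kept > 0)
    for (int m = 0; m < M; ++m) {
      delta_mean[m] /= kept; b_mean[m] /= kept; gamma_mean[m] /= kept;
    }
  return List::create(_["delta_mean"] = delta_mean, _["b_mean"] = b_mean,
                      _["gamma_mean"] = gamma_mean, _["n_kept"] = kept,
                      _["config_counts"] = cfg_counts);
}

// First-order correlated-Bernoulli haplotype chains with marginal
// frequencies f and exact adjacent correlation rho; genotypes are sums
// of two independent haplotypes.
// [[Rcpp::export(name = ".ar1_genotypes_cpp")]]
List ar1_genotypes_cpp(NumericVector f, double rho, int n_ind) {
  int M = f.size();
  IntegerMatrix geno(M, n_ind);
  long clipped = 0;
  std::vector<double> sdv(M);
  for (int m = 0; m < M; ++m) sdv[m] = std::sqrt(f[m] * (1.0 - f[m]));
  for (int i = 0; i < n_ind; ++i) {
    for (int hap = 0; hap < 2; ++hap) {
      int x = (R::unif_rand() < f[0]) ? 1 : 0;
      geno(0, i) += x;
      for (int m = 1; m < M; ++m) {
        double p = f[m] + rho * (sdv[m] / sdv[m - 1]) * ((double)x - f[m - 1]);
        if (p < 0.0) { p = 0.0; ++clipped; }
        else if (p > 1.0) { p = 1.0; ++clipped; }
        x = (R::unif_rand() < p) ? 1 : 0;
        geno(m, i) += x;
      }
    }
  }
  return List::create(_["genotypes"] = geno, _["n_clipped"] = (double)clipped);
}
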