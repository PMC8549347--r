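#include <Rcpp.h>
using namespace Rcpp;

// log(sigma(x)), stable for large |x|
static inline double log_sigmoid(double x) {
  if (x > 0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

// Systematic-scan Gibbs sampler over the binary site lattice.
//
// Each sweep visits sites in their fixed (gene-major) order and redraws
// w[i] from its full conditional
//   q1 = f1(z_i) sigma(F_i) / [f1(z_i) sigma(F_i) + f0(z_i)(1 - sigma(F_i))],
//   F_i = gamma + beta_gene * s_gene(i) + beta_cell * s_cell(i),
// with signed neighbor sums s_* computed from the current states. Uses R's
// RNG stream, so set.seed() in the caller makes runs reproducible. When
// `collect` is true, returns per-site fractions of post-burn-in sweeps with
// w = 0.
//
// [[Rcpp::export]]
List gibbs_chain_cpp(NumericVector lf0, NumericVector lf1,
                     List gene_nb, List cell_nb,
                     double gamma, double beta_gene, double beta_cell,
                     IntegerVector w_init, int n_sweeps, int burn_in,
                     bool collect) {
  const int n = w_init.size();
  if (lf0.size() != n || lf1.size() != n ||
      gene_nb.size() != n || cell_nb.size() != n) {
    stop("gibbs_chain_cpp: input length mismatch");
  }
  // flatten neighbor lists to CSR (0-based)
  std::vector<int> gptr(n + 1, 0), cptr(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    gptr[i + 1] = gptr[i] + LENGTH(VECTOR_ELT(gene_nb, i));
    cptr[i + 1] = cptr[i] + LENGTH(VECTOR_ELT(cell_nb, i));
  }
  std::vector<int> gidx(gptr[n]), cidx(cptr[n]);
  for (int i = 0; i < n; ++i) {
    IntegerVector gi = gene_nb[i];
    for (int k = 0; k < gi.size(); ++k) gidx[gptr[i] + k] = gi[k] - 1;
    IntegerVector ci = cell_nb[i];
    for (int k = 0; k < ci.size(); ++k) cidx[cptr[i] + k] = ci[k] - 1;
  }
  std::vector<int> w(w_init.begin(), w_init.end());
  std::vector<double> count0(collect ? n : 0, 0.0);
  int kept = 0;
  RNGScope scope;
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      int sg = 0, sc = 0;
      for (int k = gptr[i]; k < gptr[i + 1]; ++k) sg += 2 * w[gidx[k]] - 1;
      for (int k = cptr[i]; k < cptr[i + 1]; ++k) sc += 2 * w[cidx[k]] - 1;
      double F = gamma + beta_gene * sg + beta_cell * sc;
      double a1 = lf1[i] + log_sigmoid(F);
      double a0 = lf0[i] + log_sigmoid(-F);
      // p1 = 1 / (1 + exp(a0 - a1))
      double d = a0 - a1;
      double p1 = (d > 0) ? std::exp(-d) / (1.0 + std::exp(-d))
                          : 1.0 / (1.0 + std::exp(d));
      w[i] = (unif_rand() < p1) ? 1 : 0;
    }
    if (collect && sweep > burn_in) {
      ++kept;
      for (int i = 0; i < n; ++i) if (w[i] == 0) count0[i] += 1.0;
    }
  }
  List out = List::create(_["w"] = IntegerVector(w.begin(), w.end()));
  if (collect) {
    NumericVector p0(n);
    for (int i = 0; i < n; ++i) p0[i] = kept > 0 ? count0[i] / kept : NA_REAL;
    out["p_null"] = p0;
  }
  return out;
}

// Prior-only Gibbs sweeps: used by the simulator to couple latent DE states
// through the networks (no data term; the conditional is sigma(F)).
//
// [[Rcpp::export]]
IntegerVector gibbs_prior_cpp(List gene_nb, List cell_nb,
                              double gamma, double beta_gene, double beta_cell,
                              IntegerVector w_init, int n_sweeps) {
  const int n = w_init.size();
  std::vector<int> gptr(n + 1, 0), cptr(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    gptr[i + 1] = gptr[i] + LENGTH(VECTOR_ELT(gene_nb, i));
    cptr[i + 1] = cptr[i] + LENGTH(VECTOR_ELT(cell_nb, i));
  }
  std::vector<int> gidx(gptr[n]), cidx(cptr[n]);
  for (int i = 0; i < n; ++i) {
    IntegerVector gi = gene_nb[i];
    for (int k = 0; k < gi.size(); ++k) gidx[gptr[i] + k] = gi[k] - 1;
    IntegerVector ci = cell_nb[i];
    for (int k = 0; k < ci.size(); ++k) cidx[cptr[i] + k] = ci[k] - 1;
  }
  std::vector<int> w(w_init.begin(), w_init.end());
  RNGScope scope;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      int sg = 0, sc = 0;
      for (int k = gptr[i]; k < gptr[i + 1]; ++k) sg += 2 * w[gidx[k]] - 1;
      for (int k = cptr[i]; k < cptr[i + 1]; ++k) sc += 2 * w[cidx[k]] - 1;
      double F = gamma + beta_gene * sg + beta_cell * sc;
      double p1 = 1.0 / (1.0 + std::exp(-F));
      w[i] = (unif_rand() < p1) ? 1 : 0;
    }
  }
  return IntegerVector(w.begin(), w.end());
}
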