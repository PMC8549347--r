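# mrfDE

Network-informed, cell-type-specific differential expression for single-cell
RNA-seq.

## What it does, and for whom

Given a cells × genes count matrix with case/control labels, a gene–gene
network (e.g. protein–protein interactions) and a cell-type network (lineage
knowledge), mrfDE decides, for every (gene, cell type) *site*, whether the
gene is differentially expressed in that cell type. It is aimed at analysts
who already have cell-type annotations and want more power than per-site
tests by letting related genes and related cell types share evidence —
while keeping the false discovery rate controlled.

## The model

Per-site evidence is a z-score
`z = Φ⁻¹(F_{n1+n2−2}(t))` from a pooled-variance two-sample t-test on
log-normalized expression (or from external DE summaries via
`z = sign(lfc)·Φ⁻¹(1 − p/2)`). The z-scores follow a two-group mixture

    f(z) = π₀ f₀(z) + (1 − π₀) f₁(z),

with an empirically estimated null f₀ = N(δ₀, σ₀²) (Lindsey-smoothed
marginal, central-bulk null). The binary DE states carry a pairwise Markov
random field prior over the site lattice; the full conditional of one site is
logistic in the local field

    F = γ + β_gene Σ_{g′∈N_g} (2w_{g′c} − 1) + β_cell Σ_{c′∈N_c} (2w_{gc′} − 1).

Φ = (γ, β_gene, β_cell) is estimated by EM with a mean-field-like
approximation (M-step = weighted logistic regression); posterior null
probabilities p_gc come from a systematic-scan Gibbs sampler; DE calls use
the posterior-FDR rule `k = max{ j : (1/j) Σ_{i≤j} p_(i) ≤ α }`.

## Worked example

Simulate a benchmark dataset with known truth, run the full pipeline, and
score it:

```r
library(mrfDE)
set.seed(1)
cfg <- sim_config(n_genes = 200, n_subjects_per_group = 10,
                  n_cells_per_type_per_subject = 30, eta = 0.4, kappa = 0.2)
sim <- simulate_dataset(cfg)
norm <- normalize_log1p(suppressWarnings(
  qc_filter_cells(sim$data, min_genes = 40, max_genes = 1000)))
Z <- build_evidence_matrix(norm, cell_types = sim$cell_net$nodes)
fit <- fit_mixture(graph_z <- Z$z[Z$observed],
                   smooth_df = 10, null_method = "central_matching")
graph <- build_site_graph(Z, sim$gene_net, sim$cell_net)
em <- em_fit(fit, Z, graph, max_iter = 200, seed = 2)
post <- gibbs_posterior(fit, Z, graph, em$params,
                        n_iter = 5000, burn_in = 2500, seed = 3)
calls <- posterior_fdr_detect(post$p_null, alpha = 0.05)
truth <- sim$truth[cbind(match(graph$sites$gene, rownames(sim$truth)),
                         match(graph$sites$cell_type, colnames(sim$truth)))]
print(fit); print(em$params); print(calls)
print(round(unlist(confusion_metrics(calls$calls, truth)), 3))
```

Output (this exact run):

```
MixtureFit (central_matching null): pi0 = 0.8155, delta0 = -0.1325, sigma0 = 1.0548 (n = 3600)
MRFParams: gamma = -0.4793, beta_gene = 0.5101, beta_cell = 0.4863
DECallSet: 492 of 3600 sites rejected at alpha = 0.05
sensitivity specificity         fdr
      0.615       0.992       0.047
```

Reading it: the empirical null is close to N(0,1) with π₀ ≈ 0.82 (the
simulated DE fraction is 0.21); the fitted couplings β ≈ 0.5 recover the
generator's coupling; 492 sites are called at nominal posterior FDR 0.05 with
realized FDR 0.047. The same z-scores pushed through BH-adjusted t-tests
(`confusion_metrics(bh_adjust(2*pnorm(-abs(graph$z))) <= 0.05, truth)`) give
sensitivity 0.555 at FDR 0.049 — the network prior buys ~6 points of
sensitivity at the same realized FDR.

For real data, `cmd_fit()` (or `inst/cli/mrfde fit --config fit.cfg`) runs
the same pipeline from files on disk: counts (MTX or dense TSV), cell
metadata (`cell_id`, `cell_type`, `subject`, `group`), and two edge lists.
It writes the mixture fit, fitted MRF parameters, a per-site results table
(`gene, cell_type, z, posterior_null_prob, de_call, rank`) and a run log.

## Benchmark / acceptance

`scripts/acceptance.R` regenerates the reduced-scale benchmark from scratch
(300 genes, 18 cell types, 10 subjects/group, 30 cells per cell type per
subject, η = 0.4, κ = 0.2, λ = 2, 20 replicates; EM 200 iterations, Gibbs
5000/2500) and reports the mean empirical FDR of the pipeline at nominal
0.05:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The testthat suite additionally checks the Gibbs sampler against exact
enumeration on small lattices, EM parameter recovery on planted fields, FDR
control, the power ordering against BH-adjusted t-tests, and
threshold-sweep monotonicity (`tests/testthat/test-acceptance.R`).

See `vignettes/mrfDE-methods.Rmd` for the full model description, parameter
rationale, and limitations.
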