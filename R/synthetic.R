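# ZINB simulator with network-coupled latent DE states.
#
# The generator mirrors a case/control scRNA-seq design: per (cell type,
# subject) ZINB parameters drawn from gamma/gamma/beta hyper-distributions,
# latent site states coupled through the gene and cell-type networks by
# short prior-only Gibbs runs, and a multiplicative fold change tau in
# {lambda, 1/lambda} applied to the case-group mean at truly DE sites.

#' Draw zero-inflated negative binomial counts
#'
#' With probability `pi_zero` emits a structural zero, otherwise a negative
#' binomial draw with mean `mu` and size `phi` (variance `mu + mu^2/phi`).
#'
#' @param mu positive NB mean.
#' @param phi positive NB dispersion (size parameter).
#' @param pi_zero zero-inflation probability in \[0, 1\].
#' @param n number of draws.
#' @return integer vector of length `n`.
#' @export
sample_zinb <- function(mu, phi, pi_zero, n) {
  if (!is.finite(mu) || mu <= 0) stop("mu must be positive")
  if (!is.finite(phi) || phi <= 0) stop("phi must be positive")
  if (!is.finite(pi_zero) || pi_zero < 0 || pi_zero > 1) {
    stop("pi_zero must lie in [0, 1]")
  }
  if (n < 1L) stop("n must be >= 1")
  x <- stats::rnbinom(n, size = phi, mu = mu)
  drop <- stats::runif(n) < pi_zero
  x[drop] <- 0L
  x
}

#' Hyper-distributions of the per-(cell type, subject) ZINB parameters
#'
#' The same laws describe gene-to-gene spread and subject-to-subject
#' variability (triples are redrawn per gene for every subject), so their
#' coefficients of variation are kept modest (~10%): larger spreads turn the
#' subject redraws into pseudo-replication that inflates the pooled-cell
#' null far beyond what calibrated two-sample tests tolerate. Defaults:
#' mean ~ Gamma(100, 40) (E 2.5), dispersion ~ Gamma(100, 200) (E 0.5,
#' typical UMI-scale overdispersion), inflation ~ Beta(120, 280) (E 0.3).
#'
#' @param mean_gamma length-2 (shape, rate) of the gamma law for the mean.
#' @param disp_gamma length-2 (shape, rate) of the gamma law for the
#'   dispersion.
#' @param infl_beta length-2 (a, b) of the beta law for the zero inflation.
#' @return a `SimHyperParams` list.
#' @export
sim_hyper_params <- function(mean_gamma = c(100, 40), disp_gamma = c(100, 200),
                             infl_beta = c(120, 280)) {
  stopifnot(length(mean_gamma) == 2L, all(mean_gamma > 0),
            length(disp_gamma) == 2L, all(disp_gamma > 0),
            length(infl_beta) == 2L, all(infl_beta > 0))
  structure(list(mean_gamma = as.numeric(mean_gamma),
                 disp_gamma = as.numeric(disp_gamma),
                 infl_beta = as.numeric(infl_beta)),
            class = "SimHyperParams")
}

#' Draw ZINB parameter triples from the hyper-distributions
#'
#' One independent (mu, phi, pi_zero) triple per draw; the simulator requests
#' one per (cell type, subject).
#'
#' @param hyper a `SimHyperParams`.
#' @param n_draws number of triples.
#' @return data.frame with columns `mu`, `phi`, `pi_zero`.
#' @export
sample_celltype_params <- function(hyper, n_draws) {
  stopifnot(inherits(hyper, "SimHyperParams"), n_draws >= 0L)
  data.frame(
    mu = stats::rgamma(n_draws, hyper$mean_gamma[1L], hyper$mean_gamma[2L]),
    phi = stats::rgamma(n_draws, hyper$disp_gamma[1L], hyper$disp_gamma[2L]),
    pi_zero = stats::rbeta(n_draws, hyper$infl_beta[1L], hyper$infl_beta[2L])
  )
}

#' Generate a random gene network
#'
#' Selects `round(eta * n_genes)` genes and places random edges among only
#' those genes at the requested mean degree; unselected genes stay isolated.
#'
#' @param n_genes number of genes (nodes `g1 ... gN`).
#' @param eta fraction of genes eligible for edges, in \[0, 1\].
#' @param mean_degree target mean degree among the selected genes (default
#'   4); the number of edges is `round(n_sel * mean_degree / 2)`, capped at
#'   the complete graph.
#' @param gene_ids optional node names (default `g1..gN`).
#' @return a `NetworkSpec` over all genes.
#' @export
gen_gene_network <- function(n_genes, eta, mean_degree = 4, gene_ids = NULL) {
  stopifnot(eta >= 0, eta <= 1, n_genes >= 1L)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  n_sel <- round(eta * n_genes)
  if (n_sel < 2L) return(network_spec(gene_ids, matrix(character(), 0L, 2L)))
  sel <- sort(sample.int(n_genes, n_sel))
  n_edges <- min(round(n_sel * mean_degree / 2), n_sel * (n_sel - 1L) / 2)
  if (n_edges < 1L) return(network_spec(gene_ids, matrix(character(), 0L, 2L)))
  # sample unordered pairs without replacement via pair codes
  codes <- sample(n_sel * (n_sel - 1L) / 2, n_edges)
  # decode k -> (i, j), i < j, from the lexicographic pair index
  j <- ceiling((1 + sqrt(1 + 8 * codes)) / 2)
  i <- codes - (j - 1) * (j - 2) / 2
  network_spec(gene_ids, cbind(gene_ids[sel[i]], gene_ids[sel[j]]))
}

#' Packaged 18-cell-type immune lineage network
#'
#' Ships a fixed network over 18 immune cell types (myeloid and lymphoid
#' sub-graphs joined at antigen-presenting bridges), standing in for a
#' domain-knowledge cell network. Override by supplying an edge-list file.
#'
#' @param n_cell_types must be 18 unless `file` is given.
#' @param file optional edge-list path; when given, simply delegates to
#'   [read_edge_list()].
#' @return a `NetworkSpec` on 18 labeled nodes.
#' @export
default_cell_network <- function(n_cell_types = 18L, file = NULL) {
  if (!is.null(file)) return(read_edge_list(file))
  if (n_cell_types != 18L) {
    stop("the packaged cell network has 18 cell types; supply an edge-list ",
         "file for other sizes")
  }
  path <- system.file("extdata", "cell_network_18.tsv", package = "mrfDE",
                      mustWork = TRUE)
  read_edge_list(path)
}

#' Simulation configuration
#'
#' Defaults mirror the reference simulation design: 1000 genes, 18 cell
#' types, 15 subjects per group, 50 cells per cell type per subject,
#' fold-change parameter lambda = 2.
#'
#' @param n_genes,n_cell_types,n_subjects_per_group,n_cells_per_type_per_subject
#'   design dimensions.
#' @param eta fraction of genes connected in the generated gene network.
#' @param kappa fraction of genes initially DE.
#' @param lambda_fc fold-change magnitude (> 1); tau is lambda or 1/lambda
#'   with equal probability per site.
#' @param phi_sim `MRFParams` coupling the latent states, or NULL (default)
#'   for betas of 0.5 with a mean-field-adjusted gamma,
#'   `qlogis(kappa) - (0.5 d_gene + 0.5 d_cell)(2 kappa - 1)` with `d_*` the
#'   mean degrees of the actual networks, which keeps the marginal DE rate
#'   near kappa over the short coupling chain.
#' @param latent_sweeps prior-Gibbs sweeps applied to the initial states
#'   (default 10).
#' @param mean_degree mean degree of the generated gene network.
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(n_genes = 1000L, n_cell_types = 18L,
                       n_subjects_per_group = 15L,
                       n_cells_per_type_per_subject = 50L,
                       eta = 0.4, kappa = 0.2, lambda_fc = 2,
                       phi_sim = NULL, latent_sweeps = 10L, mean_degree = 4) {
  stopifnot(eta >= 0, eta <= 1, kappa >= 0, kappa <= 1, lambda_fc > 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_cell_types = as.integer(n_cell_types),
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_cells_per_type_per_subject =
                   as.integer(n_cells_per_type_per_subject),
                 eta = eta, kappa = kappa, lambda_fc = lambda_fc,
                 phi_sim = phi_sim, latent_sweeps = as.integer(latent_sweeps),
                 mean_degree = mean_degree),
            class = "SimulationConfig")
}

# Coupling field with gamma calibrated so the marginal DE rate stays ~ kappa.
# Starting point is the mean-field value (a site whose neighbors are i.i.d.
# Bernoulli(kappa) keeps conditional DE probability kappa); because the
# initial configuration is gene-coherent the short chain drifts, so gamma is
# then refined by bisection on the realized post-sweep marginal.
auto_phi_sim <- function(kappa, gene_net, cell_net, beta_gene = 0.5,
                         beta_cell = 0.5, sweeps = 10L, calibrate = TRUE) {
  d_gene <- 2 * nrow(gene_net$edges) / max(1L, length(gene_net$nodes))
  d_cell <- 2 * nrow(cell_net$edges) / max(1L, length(cell_net$nodes))
  base <- if (kappa <= 0) -10 else if (kappa >= 1) 10 else stats::qlogis(kappa)
  drift <- (beta_gene * d_gene + beta_cell * d_cell) * (2 * kappa - 1)
  g0 <- min(max(base - drift, -10), 10)
  if (!calibrate || kappa <= 0 || kappa >= 1) {
    return(mrf_params(g0, beta_gene, beta_cell))
  }
  realized <- function(g) {
    mean(gen_latent_states(gene_net, cell_net, kappa,
                           mrf_params(g, beta_gene, beta_cell), sweeps)$w)
  }
  lo <- g0 - 3; hi <- g0 + 3
  for (i in 1:8) {
    mid <- (lo + hi) / 2
    if (realized(mid) > kappa) hi <- mid else lo <- mid
  }
  mrf_params((lo + hi) / 2, beta_gene, beta_cell)
}

#' Generate network-coupled latent DE states
#'
#' Initializes `round(kappa * G)` randomly chosen genes as DE in every cell
#' type, then runs systematic prior-only Gibbs sweeps whose site conditional
#' is the MRF conditional under `phi_sim`, coupling states along both
#' networks.
#'
#' @param gene_net,cell_net `NetworkSpec`s; the site lattice is the full
#'   gene x cell-type grid.
#' @param kappa initial DE gene fraction in \[0, 1\].
#' @param phi_sim `MRFParams` of the coupling field.
#' @param sweeps number of Gibbs sweeps.
#' @return list with `w` (binary matrix genes x cell types) and the
#'   `SiteGraph` used.
#' @export
gen_latent_states <- function(gene_net, cell_net, kappa, phi_sim, sweeps = 10L) {
  stopifnot(kappa >= 0, kappa <= 1)
  genes <- gene_net$nodes; cts <- cell_net$nodes
  G <- length(genes); C <- length(cts)
  # full lattice: dummy all-observed evidence
  Z <- evidence_matrix(matrix(0, G, C), genes, cts)
  graph <- build_site_graph(Z, gene_net, cell_net)
  de_genes <- sample.int(G, round(kappa * G))
  w0 <- matrix(0L, G, C)
  w0[de_genes, ] <- 1L
  # site order is gene-major; flatten accordingly
  si <- site_index(Z)
  w <- w0[cbind(si$g, si$c)]
  if (sweeps > 0L) {
    w <- gibbs_prior_cpp(graph$gene_nb, graph$cell_nb, phi_sim$gamma,
                         phi_sim$beta_gene, phi_sim$beta_cell,
                         as.integer(w), as.integer(sweeps))
  }
  wm <- matrix(0L, G, C, dimnames = list(genes, cts))
  wm[cbind(si$g, si$c)] <- w
  list(w = wm, graph = graph)
}

#' Simulate a full dataset with ground truth
#'
#' Control cells draw ZINB(mu, phi, pi_zero) with per-gene parameter triples
#' redrawn from the cell type's hyper-distributions for every (cell type,
#' subject) — the hyper-laws describe the spread of per-gene estimates, and
#' the per-subject redraw carries the subject-to-subject variability that
#' makes pooled-cell tests overdispersed. Case cells at null sites
#' follow the identical law; at DE sites the mean is multiplied by tau,
#' drawn once per (gene, cell type) as lambda or 1/lambda with equal
#' probability.
#'
#' @param config a `SimulationConfig`.
#' @param hyper a `SimHyperParams`.
#' @param gene_net optional `NetworkSpec`; generated per `config` when NULL.
#' @param cell_net optional `NetworkSpec`; the packaged 18-type network when
#'   NULL.
#' @return a `SimulatedDataset`: list with `data` (`ExpressionDataset`),
#'   `truth` (genes x cell types binary matrix), `tau` (fold-change matrix),
#'   `gene_net`, `cell_net`.
#' @export
simulate_dataset <- function(config, hyper = sim_hyper_params(),
                             gene_net = NULL, cell_net = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  G <- config$n_genes; C <- config$n_cell_types
  nS <- config$n_subjects_per_group; nK <- config$n_cells_per_type_per_subject
  genes <- paste0("g", seq_len(G))
  if (is.null(gene_net)) {
    gene_net <- gen_gene_network(G, config$eta, config$mean_degree, genes)
  }
  if (is.null(cell_net)) cell_net <- default_cell_network(C)
  cts <- cell_net$nodes
  stopifnot(length(cts) == C)

  phi_sim <- config$phi_sim
  if (is.null(phi_sim)) {
    phi_sim <- auto_phi_sim(config$kappa, gene_net, cell_net)
  }
  latent <- gen_latent_states(gene_net, cell_net, config$kappa,
                              phi_sim, config$latent_sweeps)
  truth <- latent$w
  lam <- config$lambda_fc
  tau <- matrix(1, G, C, dimnames = dimnames(truth))
  de_idx <- which(truth == 1L)
  tau[de_idx] <- ifelse(stats::runif(length(de_idx)) < 0.5, lam, 1 / lam)

  n_cells <- C * 2L * nS * nK
  counts <- matrix(0L, G, n_cells)
  cell_type <- character(n_cells); subject <- character(n_cells)
  group <- character(n_cells)
  col <- 0L
  for (ci in seq_len(C)) {
    for (grp in c("case", "control")) {
      for (s in seq_len(nS)) {
        # fresh per-gene triples for every (cell type, subject): the
        # hyper-laws were fitted to per-gene estimate vectors
        pars <- sample_celltype_params(hyper, G)
        mu_g <- pars$mu
        if (grp == "case") mu_g <- mu_g * tau[, ci]
        cols <- col + seq_len(nK)
        # G x nK block fills column-major, so length-G parameter vectors
        # recycle to give each gene its own triple in every cell
        block <- matrix(stats::rnbinom(G * nK, size = pars$phi, mu = mu_g),
                        G, nK)
        block[matrix(stats::runif(G * nK) < pars$pi_zero, G, nK)] <- 0L
        counts[, cols] <- block
        cell_type[cols] <- cts[ci]
        subject[cols] <- paste0(grp, "_s", s)
        group[cols] <- grp
        col <- col + nK
      }
    }
  }
  cell_ids <- paste0("cell", seq_len(n_cells))
  meta <- data.frame(cell_id = cell_ids, cell_type = cell_type,
                     subject = subject, group = group,
                     stringsAsFactors = FALSE)
  data <- expression_dataset(counts, genes, cell_ids, meta)
  structure(list(data = data, truth = truth, tau = tau,
                 gene_net = gene_net, cell_net = cell_net, config = config),
            class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf("SimulatedDataset: %d genes x %d cells, %d cell types; true DE fraction %.3f\n",
              nrow(x$data$counts), ncol(x$data$counts),
              length(unique(x$data$cell_meta$cell_type)), mean(x$truth)))
  invisible(x)
}

#' Library-size normalization with log1p transform
#'
#' Each count becomes `log(1 + count / cell_total * scale)` (natural log,
#' scale factor 10000 by default). Cells with zero total are dropped with a
#' warning.
#'
#' @param data an `ExpressionDataset`.
#' @param scale scale factor (default 10000).
#' @return an `ExpressionDataset` whose `counts` field holds the normalized
#'   (non-integer) values; a `normalized` attribute marks it.
#' @export
normalize_log1p <- function(data, scale = 10000) {
  stopifnot(inherits(data, "ExpressionDataset"))
  tot <- Matrix::colSums(data$counts)
  keep <- tot > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-total cell(s) dropped during normalization")
    if (!any(keep)) stop("all cells have zero total counts")
  }
  m <- data$counts[, keep, drop = FALSE]
  norm <- log1p(sweep_cols(m, scale / tot[keep]))
  out <- data
  out$counts <- norm
  out$cell_ids <- data$cell_ids[keep]
  out$cell_meta <- data$cell_meta[keep, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  attr(out, "normalized") <- TRUE
  out
}

# multiply each column j of m by fac[j], preserving sparsity when sparse
sweep_cols <- function(m, fac) {
  if (inherits(m, "Matrix")) {
    m %*% Matrix::Diagonal(x = fac)
  } else {
    m * rep(fac, each = nrow(m))
  }
}

#' Quality-control cell filter
#'
#' Removes cells whose number of detected genes lies outside
#' `[min_genes, max_genes]` and cells whose mitochondrial count fraction
#' exceeds `max_mito_frac`. The mitochondrial rule is skipped (with a
#' warning) when no gene id matches `mito_prefix` — e.g. on simulated data.
#'
#' @param data an `ExpressionDataset` of raw counts.
#' @param min_genes,max_genes detected-gene bounds (defaults 200 / 5000).
#' @param max_mito_frac mitochondrial fraction cap (default 0.05).
#' @param mito_prefix gene-id prefix identifying mitochondrial genes.
#' @return the filtered `ExpressionDataset`.
#' @export
qc_filter_cells <- function(data, min_genes = 200L, max_genes = 5000L,
                            max_mito_frac = 0.05, mito_prefix = "MT-") {
  stopifnot(inherits(data, "ExpressionDataset"))
  detected <- Matrix::colSums(data$counts > 0)
  keep <- detected >= min_genes & detected <= max_genes
  mito <- startsWith(data$gene_ids, mito_prefix)
  if (any(mito)) {
    frac <- Matrix::colSums(data$counts[mito, , drop = FALSE]) /
      pmax(Matrix::colSums(data$counts), 1)
    keep <- keep & frac <= max_mito_frac
  } else {
    warning("no gene matches mito_prefix '", mito_prefix,
            "'; mitochondrial filter skipped")
  }
  if (!any(keep)) stop("QC removed all cells")
  out <- data
  out$counts <- data$counts[, keep, drop = FALSE]
  out$cell_ids <- data$cell_ids[keep]
  out$cell_meta <- data$cell_meta[keep, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  out
}
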