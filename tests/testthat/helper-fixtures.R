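# shared builders for the test suite; everything is generated in code

# hand-built MixtureFit with analytic component densities on a fine grid
make_fit <- function(delta0 = 0, sigma0 = 1,
                     f1_fun = function(x) stats::dnorm(x, 3, 1),
                     pi0 = 0.8, lim = 12, n = 4001) {
  grid <- seq(-lim, lim, length.out = n)
  mid <- (grid[-1] + grid[-n]) / 2
  f0 <- stats::dnorm(mid, delta0, sigma0)
  f1 <- f1_fun(mid)
  structure(list(grid = grid, mid = mid, f0_vals = f0,
                 f_vals = pi0 * f0 + (1 - pi0) * f1, f1_vals = f1,
                 f1_floored = rep(FALSE, length(mid)), pi0 = pi0,
                 null_params = list(delta0 = delta0, sigma0 = sigma0),
                 null_method = "manual", n = length(mid),
                 bins = n - 1L, smooth_df = NA_integer_),
            class = "MixtureFit")
}

# fit where f1 == f0 exactly (likelihood carries no information)
flat_fit <- function() make_fit(f1_fun = function(x) stats::dnorm(x, 0, 1),
                                pi0 = 0.5)

# tiny site lattice from a z matrix (NA = masked) and explicit edges
make_lattice <- function(z, gene_edges = NULL, cell_edges = NULL) {
  G <- nrow(z); C <- ncol(z)
  genes <- paste0("g", seq_len(G)); cts <- paste0("c", seq_len(C))
  dimnames(z) <- list(genes, cts)
  ge <- if (is.null(gene_edges)) matrix(character(), 0, 2)
        else cbind(genes[gene_edges[, 1]], genes[gene_edges[, 2]])
  ce <- if (is.null(cell_edges)) matrix(character(), 0, 2)
        else cbind(cts[cell_edges[, 1]], cts[cell_edges[, 2]])
  Z <- evidence_matrix(z, genes, cts)
  list(Z = Z,
       graph = build_site_graph(Z, network_spec(genes, ge),
                                network_spec(cts, ce)))
}

# small expression dataset: G genes x (2 groups x n_per cells) per cell type
make_dataset <- function(counts, cell_type, group, subject = NULL) {
  G <- nrow(counts); n <- ncol(counts)
  if (is.null(subject)) subject <- paste0(group, "_s1")
  expression_dataset(counts, paste0("g", seq_len(G)), paste0("cell", seq_len(n)),
                     data.frame(cell_id = paste0("cell", seq_len(n)),
                                cell_type = cell_type, subject = subject,
                                group = group))
}

tmpfile <- function(ext = ".tsv") tempfile(fileext = ext)
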