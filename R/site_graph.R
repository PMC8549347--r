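# Site lattice over observed (gene, cell type) hypotheses.
#
# Sites are kept in gene-major order: sorted by gene index, then cell-type
# index. This order is the fixed scan order of every systematic Gibbs sweep,
# making runs reproducible.

# gene-major (gene, cell type) index pairs of the observed sites
site_index <- function(Z) {
  obs <- which(Z$observed, arr.ind = TRUE)
  ord <- order(obs[, 1L], obs[, 2L])
  data.frame(g = obs[ord, 1L], c = obs[ord, 2L])
}

#' Build the hypothesis lattice
#'
#' Restricts the gene x cell-type grid to the observed entries of the
#' evidence matrix and wires two families of edges: gene edges connect
#' (g, c) to (g', c) when g and g' are adjacent in the gene network; cell
#' edges connect (g, c) to (g, c') when c and c' are adjacent in the
#' cell-type network. Masked sites are removed entirely; neighbor sums skip
#' them.
#'
#' @param Z an `EvidenceMatrix`.
#' @param gene_net a `NetworkSpec` over (a superset of) the gene ids; edges
#'   touching unknown genes are ignored.
#' @param cell_net a `NetworkSpec` over the cell-type ids.
#' @return a `SiteGraph`: list with `sites` (data.frame gene/cell_type and
#'   their indices), `z` (site z-scores), `gene_nb`, `cell_nb` (adjacency
#'   index lists), `A_gene`, `A_cell` (sparse adjacency matrices), `n_sites`.
#' @export
build_site_graph <- function(Z, gene_net, cell_net) {
  stopifnot(inherits(Z, "EvidenceMatrix"),
            inherits(gene_net, "NetworkSpec"),
            inherits(cell_net, "NetworkSpec"))
  si <- site_index(Z)
  n <- nrow(si)
  if (n == 0L) stop("empty lattice: no observed sites")
  # site lookup: (g, c) -> site id
  G <- length(Z$gene_ids); C <- length(Z$cell_type_ids)
  lut <- matrix(0L, G, C)
  lut[cbind(si$g, si$c)] <- seq_len(n)

  edge_pairs <- function(net, ids) {
    e <- net$edges
    if (!nrow(e)) return(matrix(integer(), 0L, 2L))
    a <- match(e[, 1L], ids); b <- match(e[, 2L], ids)
    keep <- !is.na(a) & !is.na(b)
    cbind(a[keep], b[keep])
  }
  ge <- edge_pairs(gene_net, Z$gene_ids)
  ce <- edge_pairs(cell_net, Z$cell_type_ids)

  # gene edges: for each gene-network edge (g, g') and each cell type c,
  # connect sites (g, c) ~ (g', c) when both observed
  gene_edges <- if (nrow(ge)) {
    i <- lut[cbind(rep(ge[, 1L], C), rep(seq_len(C), each = nrow(ge)))]
    j <- lut[cbind(rep(ge[, 2L], C), rep(seq_len(C), each = nrow(ge)))]
    keep <- i > 0L & j > 0L
    cbind(i[keep], j[keep])
  } else matrix(integer(), 0L, 2L)
  # cell edges: for each cell-network edge (c, c') and each gene g
  cell_edges <- if (nrow(ce)) {
    i <- lut[cbind(rep(seq_len(G), times = nrow(ce)), rep(ce[, 1L], each = G))]
    j <- lut[cbind(rep(seq_len(G), times = nrow(ce)), rep(ce[, 2L], each = G))]
    keep <- i > 0L & j > 0L
    cbind(i[keep], j[keep])
  } else matrix(integer(), 0L, 2L)

  adj <- function(edges) {
    if (!nrow(edges)) {
      return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(n, n)))
    }
    Matrix::sparseMatrix(i = c(edges[, 1L], edges[, 2L]),
                         j = c(edges[, 2L], edges[, 1L]),
                         x = 1, dims = c(n, n))
  }
  A_gene <- adj(gene_edges)
  A_cell <- adj(cell_edges)
  # column slot walk; empty columns give integer(0)
  nb_from_csc <- function(A) {
    At <- as(A, "CsparseMatrix")
    p <- At@p; iidx <- At@i
    lapply(seq_len(n), function(j) {
      if (p[j + 1L] > p[j]) iidx[(p[j] + 1L):p[j + 1L]] + 1L else integer(0)
    })
  }
  sites <- data.frame(gene = Z$gene_ids[si$g], cell_type = Z$cell_type_ids[si$c],
                      g = si$g, c = si$c, stringsAsFactors = FALSE)
  structure(list(sites = sites, z = Z$z[cbind(si$g, si$c)],
                 gene_nb = nb_from_csc(A_gene), cell_nb = nb_from_csc(A_cell),
                 A_gene = A_gene, A_cell = A_cell,
                 n_sites = n, gene_edges = gene_edges, cell_edges = cell_edges),
            class = "SiteGraph")
}

#' @export
print.SiteGraph <- function(x, ...) {
  cat(sprintf("SiteGraph: %d sites, %d gene edges, %d cell edges\n",
              x$n_sites, nrow(x$gene_edges), nrow(x$cell_edges)))
  invisible(x)
}

#' Signed neighbor sums of one site
#'
#' `s_gene = sum over gene-neighbors of (2w - 1)`; likewise `s_cell` over
#' cell-type neighbors. Sites with no neighbors contribute empty sums (0).
#'
#' @param graph a `SiteGraph`.
#' @param w binary state vector over sites.
#' @param site site index.
#' @return list with integers `s_gene`, `s_cell`.
#' @export
neighbor_sums <- function(graph, w, site) {
  stopifnot(site >= 1L, site <= graph$n_sites)
  s <- 2 * w - 1
  list(s_gene = sum(s[graph$gene_nb[[site]]]),
       s_cell = sum(s[graph$cell_nb[[site]]]))
}

# vectorized neighbor sums for all sites at once
all_neighbor_sums <- function(graph, w) {
  s <- 2 * w - 1
  list(s_gene = as.vector(graph$A_gene %*% s),
       s_cell = as.vector(graph$A_cell %*% s))
}
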