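#' Construct an expression dataset
#'
#' Bundles a genes x cells count matrix with per-cell metadata. Counts must be
#' non-negative integers; `cell_meta` must carry `cell_id`, `cell_type`,
#' `subject` and `group`, with `group` taking exactly two distinct values
#' (case/control).
#'
#' @param counts non-negative integer matrix, genes as rows, cells as columns
#'   (dense or `Matrix` sparse).
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param cell_meta data.frame with columns `cell_id`, `cell_type`, `subject`,
#'   `group`; rows are matched to `cell_ids` by `cell_id` (order free).
#' @return an object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(counts, gene_ids, cell_ids, cell_meta) {
  if (is.null(dim(counts)) || nrow(counts) != length(gene_ids) ||
      ncol(counts) != length(cell_ids)) {
    stop("counts dimensions do not match gene_ids/cell_ids lengths")
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  need <- c("cell_id", "cell_type", "subject", "group")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss)) stop("cell_meta missing column(s): ", paste(miss, collapse = ", "))
  cell_meta <- as.data.frame(cell_meta)[, need]
  absent <- setdiff(cell_ids, cell_meta$cell_id)
  if (length(absent)) {
    stop("alignment error: cell '", absent[[1]], "' present in counts but absent from metadata")
  }
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  if (anyNA(cell_meta)) stop("cell_meta contains missing values")
  groups <- unique(cell_meta$group)
  if (length(groups) != 2L) {
    stop("group must take exactly two distinct values, found: ",
         paste(groups, collapse = ", "))
  }
  validate_counts(counts)
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids), cell_meta = cell_meta),
    class = "ExpressionDataset"
  )
}

validate_counts <- function(counts) {
  x <- if (inherits(counts, "Matrix")) counts@x else as.vector(counts)
  if (length(x)) {
    if (anyNA(x) || any(x < 0)) stop("validation error: counts must be non-negative")
    if (any(x != floor(x))) stop("validation error: counts must be integers")
  }
  invisible(TRUE)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  cell types: %d | subjects: %d | groups: %s\n",
              length(unique(x$cell_meta$cell_type)),
              length(unique(x$cell_meta$subject)),
              paste(sort(unique(x$cell_meta$group)), collapse = "/")))
  invisible(x)
}

#' Construct an undirected network
#'
#' @param nodes character vector of node names.
#' @param edges two-column character matrix or data.frame of endpoints.
#'   Self-loops are dropped with a warning; duplicate edges (in either
#'   orientation) are stored once.
#' @return an object of class `NetworkSpec` with fields `nodes` (character)
#'   and `edges` (two-column character matrix, each row sorted).
#' @export
network_spec <- function(nodes, edges) {
  nodes <- unique(as.character(nodes))
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) < 2L) stop("edges must have two columns")
  if (nrow(edges)) {
    edges <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
    loops <- edges[, 1L] == edges[, 2L]
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped")
      edges <- edges[!loops, , drop = FALSE]
    }
    if (nrow(edges)) {
      bad <- !(edges[, 1L] %in% nodes) | !(edges[, 2L] %in% nodes)
      if (any(bad)) stop("edge endpoint(s) not in node set")
      # canonical orientation, then dedup
      flip <- edges[, 1L] > edges[, 2L]
      edges[flip, ] <- edges[flip, 2:1]
      edges <- unique(edges)
    }
  }
  if (!nrow(edges)) edges <- matrix(character(), 0L, 2L)
  colnames(edges) <- c("from", "to")
  structure(list(nodes = nodes, edges = edges), class = "NetworkSpec")
}

#' @export
print.NetworkSpec <- function(x, ...) {
  cat(sprintf("NetworkSpec: %d nodes, %d undirected edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Neighbors of a node in a network
#' @param net a `NetworkSpec`.
#' @param node node name.
#' @return character vector of adjacent node names.
#' @export
neighbors <- function(net, node) {
  stopifnot(inherits(net, "NetworkSpec"))
  e <- net$edges
  sort(unique(c(e[e[, 2L] == node, 1L], e[e[, 1L] == node, 2L])))
}

#' Read an undirected edge list
#'
#' Reads a whitespace- or tab-delimited two-column edge list (lines starting
#' with `#` are ignored), deduplicates edges regardless of endpoint order and
#' drops self-loops with a warning.
#'
#' @param path path to the edge-list file.
#' @param node_universe optional character vector; edges with any endpoint
#'   outside it are dropped and the number dropped is reported via `message()`.
#' @return a `NetworkSpec`; nodes are the endpoints seen (restricted to the
#'   universe when one is given, with the universe's extra nodes included so
#'   isolated genes stay addressable).
#' @export
read_edge_list <- function(path, node_universe = NULL) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    stop("parse error: line ", lineno[which(nt < 2L)[1L]],
         " has fewer than 2 tokens")
  }
  from <- vapply(toks, `[[`, character(1), 1L)
  to <- vapply(toks, `[[`, character(1), 2L)
  if (!is.null(node_universe)) {
    node_universe <- as.character(node_universe)
    ok <- from %in% node_universe & to %in% node_universe
    if (any(!ok)) {
      message(sum(!ok), " edge(s) dropped: endpoint outside node universe")
    }
    from <- from[ok]; to <- to[ok]
    nodes <- node_universe
  } else {
    nodes <- unique(c(from, to))
  }
  network_spec(nodes, cbind(from, to))
}

#' Write an edge list
#' @param net a `NetworkSpec`.
#' @param path output path; tab-delimited `from<TAB>to`, no header.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "NetworkSpec"))
  df <- as.data.frame(net$edges)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a count matrix plus cell metadata
#'
#' Counts may be MatrixMarket (`.mtx`, with sibling `features`/`barcodes`
#' files) or dense CSV/TSV with gene rows and cell columns (first column =
#' gene id). Metadata is a TSV/CSV with columns `cell_id`, `cell_type`,
#' `subject`, `group`.
#'
#' @param counts_path path to the matrix (`.mtx` or delimited text).
#' @param meta_path path to the metadata table.
#' @param features_path,barcodes_path row/column id files for the MTX route;
#'   default to `features.tsv` / `barcodes.tsv` next to the matrix.
#' @param genes_as_rows set `FALSE` if the matrix is cells x genes.
#' @return an `ExpressionDataset`.
#' @export
read_expression <- function(counts_path, meta_path,
                            features_path = NULL, barcodes_path = NULL,
                            genes_as_rows = TRUE) {
  if (!file.exists(counts_path)) stop("cannot read counts: ", counts_path)
  if (!file.exists(meta_path)) stop("cannot read metadata: ", meta_path)
  if (grepl("\\.mtx$", counts_path, ignore.case = TRUE)) {
    m <- as(Matrix::readMM(counts_path), "CsparseMatrix")
    dir <- dirname(counts_path)
    if (is.null(features_path)) features_path <- file.path(dir, "features.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.tsv")
    if (!file.exists(features_path)) stop("cannot read features: ", features_path)
    if (!file.exists(barcodes_path)) stop("cannot read barcodes: ", barcodes_path)
    rows <- data.table::fread(features_path, header = FALSE)[[1L]]
    cols <- data.table::fread(barcodes_path, header = FALSE)[[1L]]
  } else {
    dt <- data.table::fread(counts_path, header = TRUE)
    rows <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    cols <- colnames(m)
  }
  if (!genes_as_rows) {
    m <- Matrix::t(m)
    tmp <- rows; rows <- cols; cols <- tmp
  }
  if (nrow(m) != length(rows)) {
    stop("alignment error: ", nrow(m), " matrix rows vs ", length(rows), " gene ids")
  }
  if (ncol(m) != length(cols)) {
    stop("alignment error: ", ncol(m), " matrix columns vs ", length(cols), " cell ids")
  }
  meta <- as.data.frame(data.table::fread(meta_path, header = TRUE,
                                          colClasses = "character"))
  expression_dataset(m, rows, cols, meta)
}

#' Write a dataset as dense TSV + metadata TSV
#' @param data an `ExpressionDataset`.
#' @param counts_path,meta_path output paths.
#' @export
write_expression <- function(data, counts_path, meta_path) {
  stopifnot(inherits(data, "ExpressionDataset"))
  dt <- data.table::data.table(gene = data$gene_ids)
  cm <- as.matrix(data$counts)
  storage.mode(cm) <- "integer"
  dt <- cbind(dt, data.table::as.data.table(cm))
  data.table::fwrite(dt, counts_path, sep = "\t")
  data.table::fwrite(data$cell_meta, meta_path, sep = "\t")
  invisible(counts_path)
}

#' Write per-site results
#'
#' @param results data.frame with columns `gene`, `cell_type`, `z`,
#'   `posterior_null_prob`, `de_call` (plus optional extras such as `rank`).
#' @param path output TSV path.
#' @return the path, invisibly; the written file round-trips through
#'   [read_results()].
#' @export
write_results <- function(results, path) {
  need <- c("gene", "cell_type", "z", "posterior_null_prob", "de_call")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results missing column(s): ", paste(miss, collapse = ", "))
  results <- as.data.frame(results)[, c(need, setdiff(names(results), need))]
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: ", path)
  data.table::fwrite(results, path, sep = "\t")
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("cannot read results: ", path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}
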