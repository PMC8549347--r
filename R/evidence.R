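#' Pooled two-sample t-statistic
#'
#' Student t with pooled variance; the degrees of freedom `n1 + n2 - 2` are
#' the ones the z-transform uses downstream.
#'
#' @param y1,y2 numeric vectors of (normalized) expression for the two groups,
#'   each of length >= 2.
#' @return list with `t` and `df`.
#' @export
pooled_t_statistic <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2)
  if (n1 < 2L || n2 < 2L) {
    stop("undefined statistic: each group needs at least 2 observations")
  }
  v1 <- stats::var(y1); v2 <- stats::var(y2)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    stop("undefined statistic: zero pooled variance")
  }
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = (mean(y1) - mean(y2)) / se, df = n1 + n2 - 2L)
}

#' Transform a t-statistic to a z-score
#'
#' `z = qnorm(pt(t, df))`, clipped to `[-z_max, z_max]` to avoid infinities
#' from CDF saturation.
#'
#' @param t t-statistic (finite).
#' @param df degrees of freedom (>= 1).
#' @param z_max clipping bound; the normal quantile saturates in double
#'   precision near |z| = 8.2, so the default 10 only guards true overflow.
#' @return z-score.
#' @export
t_to_z <- function(t, df, z_max = 10) {
  if (any(!is.finite(t))) stop("non-finite t-statistic")
  if (any(df < 1)) stop("df must be >= 1")
  # evaluate in the tail-stable direction to keep antisymmetry exact
  z <- ifelse(t <= 0,
              stats::qnorm(stats::pt(t, df, lower.tail = TRUE), lower.tail = TRUE),
              -stats::qnorm(stats::pt(t, df, lower.tail = FALSE), lower.tail = TRUE))
  pmin(pmax(z, -z_max), z_max)
}

#' Convert a signed two-sided p-value to a z-score
#'
#' For external DE summaries (e.g. Wilcoxon or hurdle-model output):
#' `z = sign * qnorm(1 - p/2)`, with the sign taken from the log-fold change.
#'
#' @param p two-sided p-value in (0, 1]; floored at 1e-300 before the
#'   transform.
#' @param sign -1 or +1 (sign of the log-fold change); 0 is accepted and
#'   yields z = 0.
#' @param z_max clipping bound (see [t_to_z()]).
#' @param two_sided set `FALSE` if `p` is one-sided (then `z = sign *
#'   qnorm(1 - p)`).
#' @return z-score.
#' @export
signed_p_to_z <- function(p, sign, z_max = 10, two_sided = TRUE) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p <- pmax(p, 1e-300)
  mag <- if (two_sided) stats::qnorm(p / 2, lower.tail = FALSE)
         else stats::qnorm(p, lower.tail = FALSE)
  z <- base::sign(sign) * mag
  pmin(pmax(z, -z_max), z_max)
}

#' Build the gene x cell-type evidence matrix
#'
#' For every (gene, cell type) site, pools all cells of that type by group
#' (across subjects), computes the pooled t-statistic and transforms it to a
#' z-score. Sites where a group has fewer than 2 cells, or where the pooled
#' variance is zero, are masked.
#'
#' @param data a normalized `ExpressionDataset` (see [normalize_log1p()]).
#' @param genes,cell_types optional ordered label subsets; default to all
#'   genes / all cell types present in `data` (cell types in sorted order).
#' @param case_group which `group` level is "case" (goes first in the mean
#'   difference); defaults to the alphabetically later level so that e.g.
#'   case/control orders as expected with explicit labels.
#' @param z_max clipping bound passed to [t_to_z()].
#' @return an `EvidenceMatrix`: list with `z` (G x C numeric, NA where
#'   masked), `observed` (logical mask), `gene_ids`, `cell_type_ids`.
#' @export
build_evidence_matrix <- function(data, genes = NULL, cell_types = NULL,
                                  case_group = NULL, z_max = 10) {
  stopifnot(inherits(data, "ExpressionDataset"))
  if (is.null(genes)) genes <- data$gene_ids
  if (is.null(cell_types)) cell_types <- sort(unique(data$cell_meta$cell_type))
  groups <- sort(unique(data$cell_meta$group))
  if (is.null(case_group)) case_group <- groups[[1L]]
  if (!case_group %in% groups) stop("unknown case_group: ", case_group)
  ctrl_group <- setdiff(groups, case_group)
  G <- length(genes); C <- length(cell_types)
  z <- matrix(NA_real_, G, C, dimnames = list(genes, cell_types))
  gidx <- match(genes, data$gene_ids)
  if (anyNA(gidx)) stop("gene(s) not in dataset: ", genes[which(is.na(gidx))[1L]])
  X <- data$counts[gidx, , drop = FALSE]
  for (j in seq_len(C)) {
    ct <- cell_types[[j]]
    in_ct <- data$cell_meta$cell_type == ct
    i1 <- which(in_ct & data$cell_meta$group == case_group)
    i2 <- which(in_ct & data$cell_meta$group == ctrl_group)
    n1 <- length(i1); n2 <- length(i2)
    if (n1 < 2L || n2 < 2L) {
      warning("cell type '", ct, "' has <2 cells in a group; column masked")
      next
    }
    x1 <- X[, i1, drop = FALSE]; x2 <- X[, i2, drop = FALSE]
    m1 <- Matrix::rowMeans(x1); m2 <- Matrix::rowMeans(x2)
    ss1 <- Matrix::rowSums(x1 * x1) - n1 * m1^2
    ss2 <- Matrix::rowSums(x2 * x2) - n2 * m2^2
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    ok <- is.finite(se) & se > sqrt(.Machine$double.eps) * (abs(m1) + abs(m2) + 1)
    tt <- (m1 - m2)[ok] / se[ok]
    z[ok, j] <- t_to_z(tt, n1 + n2 - 2L, z_max = z_max)
  }
  evidence_matrix(z, genes, cell_types)
}

#' Construct an evidence matrix from a z-score matrix
#' @param z numeric G x C matrix; `NA` marks masked (unobserved) sites.
#' @param gene_ids,cell_type_ids ordered labels.
#' @return an `EvidenceMatrix`.
#' @export
evidence_matrix <- function(z, gene_ids, cell_type_ids) {
  z <- as.matrix(z)
  stopifnot(nrow(z) == length(gene_ids), ncol(z) == length(cell_type_ids))
  observed <- is.finite(z)
  z[!observed] <- NA_real_
  dimnames(z) <- list(gene_ids, cell_type_ids)
  dimnames(observed) <- dimnames(z)
  structure(list(z = z, observed = observed,
                 gene_ids = as.character(gene_ids),
                 cell_type_ids = as.character(cell_type_ids)),
            class = "EvidenceMatrix")
}

#' @export
print.EvidenceMatrix <- function(x, ...) {
  cat(sprintf("EvidenceMatrix: %d genes x %d cell types (%d observed sites)\n",
              length(x$gene_ids), length(x$cell_type_ids), sum(x$observed)))
  invisible(x)
}

#' Build an evidence matrix from external DE summaries
#'
#' @param summaries data.frame with columns `gene`, `cell_type`, `p_value`,
#'   `log_fold_change` (one row per site; missing sites are masked).
#' @param genes,cell_types ordered label lists; default to the sorted unique
#'   values present.
#' @param z_max,two_sided passed to [signed_p_to_z()].
#' @return an `EvidenceMatrix`.
#' @export
evidence_from_summaries <- function(summaries, genes = NULL, cell_types = NULL,
                                    z_max = 10, two_sided = TRUE) {
  need <- c("gene", "cell_type", "p_value", "log_fold_change")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("summaries missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(genes)) genes <- sort(unique(summaries$gene))
  if (is.null(cell_types)) cell_types <- sort(unique(summaries$cell_type))
  z <- matrix(NA_real_, length(genes), length(cell_types),
              dimnames = list(genes, cell_types))
  gi <- match(summaries$gene, genes)
  ci <- match(summaries$cell_type, cell_types)
  keep <- !is.na(gi) & !is.na(ci) & is.finite(summaries$p_value)
  z[cbind(gi[keep], ci[keep])] <-
    signed_p_to_z(summaries$p_value[keep], sign(summaries$log_fold_change[keep]),
                  z_max = z_max, two_sided = two_sided)
  evidence_matrix(z, genes, cell_types)
}

#' Serialize an evidence matrix as TSV (genes as rows, empty cell = masked)
#' @param Z an `EvidenceMatrix`.
#' @param path output path.
#' @export
write_evidence <- function(Z, path) {
  stopifnot(inherits(Z, "EvidenceMatrix"))
  dt <- data.table::data.table(gene = Z$gene_ids)
  dt <- cbind(dt, data.table::as.data.table(Z$z))
  data.table::fwrite(dt, path, sep = "\t", na = "")
  invisible(path)
}

#' Read an evidence matrix written by [write_evidence()]
#' @param path TSV path.
#' @return an `EvidenceMatrix`.
#' @export
read_evidence <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  genes <- as.character(dt[[1L]])
  z <- as.matrix(dt[, -1L, drop = FALSE])
  evidence_matrix(z, genes, colnames(z))
}
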