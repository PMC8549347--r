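#' Posterior-FDR detection rule
#'
#' Sorts the posterior null probabilities ascending and rejects the largest
#' prefix whose running mean stays at or below `alpha`:
#' `k = max { j : (1/j) sum_{i<=j} p_(i) <= alpha }` (k = 0 when even the
#' smallest value exceeds `alpha`). Ties at the boundary are resolved by a
#' stable sort on (p_null, site index), so calls are deterministic and
#' order-invariant.
#'
#' @param p_null numeric vector of posterior null probabilities in \[0, 1\].
#' @param alpha nominal posterior FDR level in (0, 1).
#' @return a `DECallSet`: list with `calls` (logical vector in input order),
#'   `alpha`, `k`, and `rank` (1 = smallest p_null).
#' @export
posterior_fdr_detect <- function(p_null, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  n <- length(p_null)
  if (n == 0L) {
    return(structure(list(calls = logical(0), alpha = alpha, k = 0L,
                          rank = integer(0)), class = "DECallSet"))
  }
  if (anyNA(p_null) || any(p_null < 0 | p_null > 1)) {
    stop("p_null values must lie in [0, 1]")
  }
  ord <- order(p_null, seq_len(n))
  cm <- cumsum(p_null[ord]) / seq_len(n)
  ok <- which(cm <= alpha)
  k <- if (length(ok)) max(ok) else 0L
  calls <- logical(n)
  if (k > 0L) calls[ord[seq_len(k)]] <- TRUE
  rank <- integer(n); rank[ord] <- seq_len(n)
  structure(list(calls = calls, alpha = alpha, k = as.integer(k), rank = rank),
            class = "DECallSet")
}

#' @export
print.DECallSet <- function(x, ...) {
  cat(sprintf("DECallSet: %d of %d sites rejected at alpha = %g\n",
              x$k, length(x$calls), x$alpha))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (monotone-enforced), for the comparator
#' pipelines.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Confusion-matrix metrics of a call set against ground truth
#'
#' Sensitivity = TP/(TP+FN); specificity = TN/(TN+FP);
#' FDR = FP/(TP+FP), defined as 0 when nothing is called.
#'
#' @param calls logical (or 0/1) vector of DE calls.
#' @param truth logical (or 0/1) vector of true DE states, same length.
#' @return list with `sensitivity`, `specificity`, `fdr`.
#' @export
confusion_metrics <- function(calls, truth) {
  if (length(calls) != length(truth)) stop("calls and truth differ in length")
  calls <- as.logical(calls); truth <- as.logical(truth)
  tp <- sum(calls & truth); fp <- sum(calls & !truth)
  fn <- sum(!calls & truth); tn <- sum(!calls & !truth)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
       specificity = if (tn + fp > 0) tn / (tn + fp) else 1,
       fdr = fp / max(1, tp + fp))
}
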