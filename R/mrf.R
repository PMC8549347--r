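# Pairwise MRF over the site lattice.
#
# The prior rewards agreement of the binary DE states along gene edges
# (weight beta_gene) and cell-type edges (weight beta_cell), with a global
# abundance parameter gamma (the difference of the two state potentials; the
# individual state potentials are non-identifiable). The full conditional of
# one site is logistic in the field
#   F = gamma + beta_gene * s_gene + beta_cell * s_cell,
# where s_* are the signed neighbor sums (+1 for a DE neighbor, -1 for a
# null neighbor).

#' MRF prior parameters
#' @param gamma real scalar; log prior odds of DE for an isolated site.
#' @param beta_gene,beta_cell nonnegative coupling strengths along gene and
#'   cell-type edges.
#' @param beta_max box bound checked on the betas (default 5).
#' @return an `MRFParams` list.
#' @export
mrf_params <- function(gamma, beta_gene, beta_cell, beta_max = 5) {
  stopifnot(is.finite(gamma), is.finite(beta_gene), is.finite(beta_cell))
  if (beta_gene < 0 || beta_cell < 0) stop("beta parameters must be >= 0")
  if (beta_gene > beta_max || beta_cell > beta_max) {
    stop("beta parameters exceed beta_max = ", beta_max)
  }
  structure(list(gamma = gamma, beta_gene = beta_gene, beta_cell = beta_cell),
            class = "MRFParams")
}

#' @export
print.MRFParams <- function(x, ...) {
  cat(sprintf("MRFParams: gamma = %.4f, beta_gene = %.4f, beta_cell = %.4f\n",
              x$gamma, x$beta_gene, x$beta_cell))
  invisible(x)
}

log_sigmoid <- function(x) ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))

#' Conditional DE probability of a site given its neighbors
#'
#' `P(w = 1 | rest) = plogis(F)` with
#' `F = gamma + beta_gene * s_gene + beta_cell * s_cell`.
#'
#' @param params an `MRFParams`.
#' @param s_gene,s_cell signed neighbor sums (see [neighbor_sums()]).
#' @return probability in (0, 1); vectorized over the sums.
#' @export
conditional_prob <- function(params, s_gene, s_cell) {
  F <- params$gamma + params$beta_gene * s_gene + params$beta_cell * s_cell
  stats::plogis(F)
}

#' Posterior state split of one site given data and neighbors
#'
#' `q1` is proportional to `f1(z) * P(w=1|neighbors)` and `q0` to
#' `f0(z) * P(w=0|neighbors)`; the pair is normalized to sum to 1.
#'
#' @param fit a `MixtureFit`.
#' @param z site z-score(s).
#' @param params an `MRFParams`.
#' @param s_gene,s_cell signed neighbor sums.
#' @return list with vectors `q0`, `q1`.
#' @export
site_posterior <- function(fit, z, params, s_gene, s_cell) {
  F <- params$gamma + params$beta_gene * s_gene + params$beta_cell * s_cell
  a1 <- log(pmax(eval_f1(fit, z), 0)) + log_sigmoid(F)
  a0 <- log(pmax(eval_f0(fit, z), 0)) + log_sigmoid(-F)
  bad <- !is.finite(a0) & !is.finite(a1)
  if (any(bad)) {
    warning("both mixture densities vanish at some z; using prior conditional")
    a1[bad] <- log_sigmoid(F[bad]); a0[bad] <- log_sigmoid(-F[bad])
  }
  q1 <- stats::plogis(a1 - a0)
  list(q0 = 1 - q1, q1 = q1)
}

# field values for all sites given a fixed configuration w_tilde
site_fields <- function(graph, w_tilde, params) {
  s <- all_neighbor_sums(graph, w_tilde)
  params$gamma + params$beta_gene * s$s_gene + params$beta_cell * s$s_cell
}

#' EM objective for the prior parameters
#'
#' Expected complete-data log-likelihood of the prior term: posterior weights
#' `(q0, q1)` are computed under `params_post` while the log conditionals use
#' `params_free`; both use neighbor sums from the fixed configuration
#' `w_tilde`. Log probabilities are floored at 1e-12.
#'
#' @param fit a `MixtureFit`.
#' @param Z an `EvidenceMatrix` (only used for alignment checks).
#' @param graph a `SiteGraph`.
#' @param w_tilde fixed binary configuration over sites.
#' @param params_post parameters of the weights (current estimate).
#' @param params_free parameters being scored (free argument).
#' @return scalar objective value (finite).
#' @export
q_function <- function(fit, Z, graph, w_tilde, params_post, params_free) {
  s <- all_neighbor_sums(graph, w_tilde)
  q <- site_posterior(fit, graph$z, params_post, s$s_gene, s$s_cell)
  Ff <- params_free$gamma + params_free$beta_gene * s$s_gene +
    params_free$beta_cell * s$s_cell
  l1 <- pmax(log_sigmoid(Ff), log(1e-12))
  l0 <- pmax(log_sigmoid(-Ff), log(1e-12))
  sum(q$q0 * l0 + q$q1 * l1)
}

# weighted-logistic maximization used by m_step: weights (q0, q1), fixed
# covariates (1, s_gene, s_cell)
optimize_params <- function(q1, s_gene, s_cell, gamma_max, beta_max, start) {
  negQ <- function(par) {
    F <- par[1L] + par[2L] * s_gene + par[3L] * s_cell
    -sum(q1 * log_sigmoid(F) + (1 - q1) * log_sigmoid(-F))
  }
  grad <- function(par) {
    F <- par[1L] + par[2L] * s_gene + par[3L] * s_cell
    r <- stats::plogis(F) - q1
    c(sum(r), sum(r * s_gene), sum(r * s_cell))
  }
  fit <- stats::optim(start, negQ, grad, method = "L-BFGS-B",
                      lower = c(-gamma_max, 0, 0),
                      upper = c(gamma_max, beta_max, beta_max),
                      control = list(maxit = 200L))
  if (!fit$convergence %in% c(0L, 52L)) {
    stop("M-step optimizer failed to converge (code ", fit$convergence,
         "); last iterate: ", paste(signif(fit$par, 4), collapse = ", "))
  }
  fit$par
}

#' M-step: maximize the EM objective over the prior parameters
#'
#' Equivalent to a weighted logistic regression of the posterior weights on
#' the covariates (1, s_gene, s_cell); the problem is concave and solved with
#' a box-constrained quasi-Newton method.
#'
#' @inheritParams q_function
#' @param params_post current parameter estimate (weights).
#' @param gamma_max,beta_max box bounds; estimates within 1e-6 of a bound are
#'   flagged via the `at_bound` attribute.
#' @return an `MRFParams` with attribute `at_bound` (logical).
#' @export
m_step <- function(fit, Z, graph, w_tilde, params_post,
                   gamma_max = 10, beta_max = 5) {
  if (graph$n_sites < 1L) stop("empty lattice")
  s <- all_neighbor_sums(graph, w_tilde)
  q <- site_posterior(fit, graph$z, params_post, s$s_gene, s$s_cell)
  start <- c(params_post$gamma, params_post$beta_gene, params_post$beta_cell)
  start[1L] <- min(max(start[1L], -gamma_max), gamma_max)
  start[2:3] <- pmin(pmax(start[2:3], 0), beta_max)
  par <- optimize_params(q$q1, s$s_gene, s$s_cell, gamma_max, beta_max, start)
  out <- mrf_params(par[1L], par[2L], par[3L], beta_max = beta_max)
  attr(out, "at_bound") <- abs(par[1L]) > gamma_max - 1e-6 |
    par[2:3] > beta_max - 1e-6
  out
}

#' Fit the MRF prior by EM with a mean-field-like approximation
#'
#' Alternates: (E) posterior state weights from the current parameters and
#' the neighbor sums of a fixed configuration; (M) weighted-logistic update
#' of the parameters; (refresh) one or more systematic Gibbs sweeps of the
#' configuration under the updated parameters, with posterior proportional
#' to `f(z|w) * P(w | neighbors)`. The mixture fit (step 1) is supplied by
#' the caller.
#'
#' @param fit a `MixtureFit`.
#' @param Z an `EvidenceMatrix`.
#' @param graph a `SiteGraph` built from `Z`.
#' @param max_iter iteration cap (default 200, the reference run length).
#' @param gibbs_sweeps_per_iter configuration-refresh sweeps per iteration.
#' @param tol convergence tolerance: stop early when `max |delta Phi| < tol`
#'   for 5 consecutive iterations.
#' @param seed integer seed governing the refresh sweeps.
#' @param gamma_max,beta_max box bounds for the M-step.
#' @return list with `params` (`MRFParams`), `trajectory` (iterations x 3
#'   matrix), `converged`, `n_iter`, `w_tilde` (final configuration), `seed`.
#' @export
em_fit <- function(fit, Z, graph, max_iter = 200L, gibbs_sweeps_per_iter = 1L,
                   tol = 1e-4, seed = 1L, gamma_max = 10, beta_max = 5) {
  stopifnot(inherits(graph, "SiteGraph"))
  if (graph$n_sites < 1L) stop("empty lattice: no observed sites")
  set.seed(seed)
  lf0 <- log(pmax(eval_f0(fit, graph$z), 1e-300))
  lf1 <- log(pmax(eval_f1(fit, graph$z), 1e-300))
  w <- initial_config(fit, Z)
  stopifnot(length(w) == graph$n_sites)
  p1 <- min(max(mean(w), 1e-3), 1 - 1e-3)
  params <- mrf_params(stats::qlogis(p1), 0, 0, beta_max = beta_max)
  traj <- matrix(NA_real_, max_iter, 3L,
                 dimnames = list(NULL, c("gamma", "beta_gene", "beta_cell")))
  streak <- 0L; converged <- FALSE; used <- 0L
  for (k in seq_len(max_iter)) {
    new_params <- m_step(fit, Z, graph, w, params,
                         gamma_max = gamma_max, beta_max = beta_max)
    delta <- max(abs(c(new_params$gamma - params$gamma,
                       new_params$beta_gene - params$beta_gene,
                       new_params$beta_cell - params$beta_cell)))
    params <- new_params
    traj[k, ] <- c(params$gamma, params$beta_gene, params$beta_cell)
    used <- k
    # EM step 4: refresh the configuration under the updated parameters
    chain <- gibbs_chain_cpp(lf0, lf1, graph$gene_nb, graph$cell_nb,
                             params$gamma, params$beta_gene, params$beta_cell,
                             as.integer(w), gibbs_sweeps_per_iter, 0L, FALSE)
    w <- chain$w
    streak <- if (delta < tol) streak + 1L else 0L
    if (streak >= 5L) { converged <- TRUE; break }
  }
  list(params = params, trajectory = traj[seq_len(used), , drop = FALSE],
       converged = converged, n_iter = used, w_tilde = w, seed = seed)
}

#' Posterior DE probabilities by Gibbs sampling
#'
#' Systematic-scan Gibbs sampler over the site lattice in the fixed
#' gene-major order, with each site drawn from its full conditional
#' `q1 = f1(z) sigma(F) / [f1(z) sigma(F) + f0(z) (1 - sigma(F))]`.
#' The per-site posterior null probability is the fraction of post-burn-in
#' sweeps with `w = 0`. Deterministic given the seed.
#'
#' @param fit a `MixtureFit`.
#' @param Z an `EvidenceMatrix`.
#' @param graph a `SiteGraph` built from `Z`.
#' @param params fitted `MRFParams`.
#' @param n_iter total sweeps (default 20000, the reference schedule).
#' @param burn_in discarded sweeps (default 10000).
#' @param seed integer seed.
#' @param init optional initial configuration; defaults to
#'   [initial_config()].
#' @return a `PosteriorMatrix`: list with `p_null` over sites, `sites`,
#'   `n_samples`, `burn_in`, `seed`.
#' @export
gibbs_posterior <- function(fit, Z, graph, params, n_iter = 20000L,
                            burn_in = 10000L, seed = 1L, init = NULL) {
  stopifnot(n_iter > burn_in)
  if (graph$n_sites < 1L) stop("empty lattice: no observed sites")
  set.seed(seed)
  lf0 <- log(pmax(eval_f0(fit, graph$z), 1e-300))
  lf1 <- log(pmax(eval_f1(fit, graph$z), 1e-300))
  w <- if (is.null(init)) initial_config(fit, Z) else as.integer(init)
  stopifnot(length(w) == graph$n_sites)
  chain <- gibbs_chain_cpp(lf0, lf1, graph$gene_nb, graph$cell_nb,
                           params$gamma, params$beta_gene, params$beta_cell,
                           as.integer(w), as.integer(n_iter),
                           as.integer(burn_in), TRUE)
  structure(list(p_null = chain$p_null, sites = graph$sites,
                 n_samples = as.integer(n_iter), burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "PosteriorMatrix")
}

#' @export
print.PosteriorMatrix <- function(x, ...) {
  cat(sprintf("PosteriorMatrix: %d sites, %d sweeps (%d burn-in), seed %d\n",
              length(x$p_null), x$n_samples, x$burn_in, x$seed))
  invisible(x)
}

#' Exact posterior null probabilities by enumeration (test oracle)
#'
#' Sums the unnormalized joint over all `2^n` configurations:
#' `prod_i f_{w_i}(z_i) * exp(gamma sum w + beta_gene * #agreeing gene edges
#' + beta_cell * #agreeing cell edges)`. Intended as an independent check of
#' the Gibbs sampler on tiny lattices.
#'
#' @inheritParams gibbs_posterior
#' @return numeric vector of exact `P(w = 0 | Z)` per site.
#' @export
enumerate_exact <- function(fit, Z, graph, params) {
  n <- graph$n_sites
  if (n > 20L) stop("refusing to enumerate more than 20 sites (got ", n, ")")
  lf0 <- log(pmax(eval_f0(fit, graph$z), 1e-300))
  lf1 <- log(pmax(eval_f1(fit, graph$z), 1e-300))
  nc <- 2L^n
  W <- matrix(0L, nc, n)
  for (j in seq_len(n)) {
    W[, j] <- bitwAnd(bitwShiftR(seq_len(nc) - 1L, j - 1L), 1L)
  }
  logw <- W %*% lf1 + (1 - W) %*% lf0 + params$gamma * rowSums(W)
  agree_count <- function(edges) {
    if (!nrow(edges)) return(0)
    ac <- numeric(nc)
    for (r in seq_len(nrow(edges))) {
      ac <- ac + (W[, edges[r, 1L]] == W[, edges[r, 2L]])
    }
    ac
  }
  logw <- logw + params$beta_gene * agree_count(graph$gene_edges) +
    params$beta_cell * agree_count(graph$cell_edges)
  wgt <- exp(logw - max(logw))
  wgt <- wgt / sum(wgt)
  as.vector(crossprod(1 - W, wgt))
}

#' Write fitted MRF parameters as a key-value file
#' @param result output of [em_fit()] (or an `MRFParams`).
#' @param path output path.
#' @param extra named list of additional scalar fields to record.
#' @export
write_mrf_params <- function(result, path, extra = list()) {
  if (inherits(result, "MRFParams")) {
    result <- list(params = result, converged = NA, n_iter = NA, seed = NA)
  }
  kv <- c(gamma = result$params$gamma,
          beta_gene = result$params$beta_gene,
          beta_cell = result$params$beta_cell,
          converged = result$converged, n_iter = result$n_iter,
          seed = result$seed, extra)
  writeLines(paste0(names(kv), ": ", unlist(kv)), path)
  invisible(path)
}

#' Read MRF parameters from a key-value file
#' @param path path written by [write_mrf_params()].
#' @return an `MRFParams`.
#' @export
read_mrf_params <- function(path) {
  kv <- read_keyvalue(path)
  mrf_params(as.numeric(kv$gamma), as.numeric(kv$beta_gene),
             as.numeric(kv$beta_cell))
}
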