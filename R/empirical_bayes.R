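#' Fit the two-group mixture on pooled z-scores
#'
#' Estimates the marginal density f of the z-scores by Lindsey's device
#' (Poisson regression of histogram counts on a natural-spline basis), an
#' empirical null N(delta0, sigma0^2) with null proportion pi0 from the
#' central bulk, and the non-null density f1 = (f - pi0 f0) / (1 - pi0),
#' floored at zero.
#'
#' @param z_values numeric vector of observed z-scores (non-finite dropped).
#' @param bins number of histogram bins (default 120).
#' @param smooth_df degrees of freedom of the natural-spline marginal
#'   (default 7).
#' @param null_method `"mle"` (truncated-normal maximum likelihood on the
#'   central quantile range), `"central_matching"` (quadratic fit to log f
#'   around its central peak), or `"theoretical"` (N(0,1) null, pi0 from the
#'   central-density ratio).
#' @param central_frac optional fixed central fraction for the MLE null
#'   window; NULL (default) uses the sample-size-adaptive window
#'   `median(z) +/- 4.3 exp(-0.26 log10 n)` robust SDs.
#' @param f1_floor floor applied to f1 before renormalization; keeps later
#'   Gibbs updates from locking out states with exactly-zero likelihood.
#' @return a `MixtureFit`: list with `grid` (bin breakpoints), `mid`
#'   (midpoints), `f0_vals`, `f_vals`, `f1_vals` (densities at midpoints),
#'   `pi0`, `null_params` (`delta0`, `sigma0`), and the call settings.
#' @export
fit_mixture <- function(z_values, bins = 120L, smooth_df = 7L,
                        null_method = c("mle", "central_matching", "theoretical"),
                        central_frac = NULL, f1_floor = 1e-12) {
  null_method <- match.arg(null_method)
  z <- z_values[is.finite(z_values)]
  if (!length(z)) stop("no finite z-values")
  if (stats::sd(z) == 0) stop("degenerate z-values: all equal")
  if (length(z) < 200L && null_method != "theoretical") {
    warning("fewer than 200 z-values; falling back to theoretical null")
    null_method <- "theoretical"
  }
  n <- length(z)
  lo <- min(z) - 1e-8; hi <- max(z) + 1e-8
  grid <- seq(lo, hi, length.out = bins + 1L)
  width <- grid[2L] - grid[1L]
  mid <- (grid[-1L] + grid[-length(grid)]) / 2
  counts <- as.vector(table(cut(z, grid, include.lowest = TRUE)))

  # Lindsey's device: Poisson spline fit to bin counts -> smooth marginal f
  basis <- splines::ns(mid, df = smooth_df)
  pois <- suppressWarnings(
    stats::glm(counts ~ basis, family = stats::poisson())
  )
  f_vals <- as.vector(stats::fitted(pois)) / (n * width)

  np <- switch(null_method,
    mle = null_mle(z, central_frac),
    central_matching = null_central_matching(mid, f_vals, z),
    theoretical = list(delta0 = 0, sigma0 = 1, pi0 = NA_real_)
  )
  if (null_method == "mle" && is.finite(np$pi0) && np$pi0 > 1) {
    # an MLE null that overexplains the marginal (pi0 > 1) is inadmissible;
    # central matching is more robust when the non-null fraction is large
    warning("MLE null gave pi0 = ", round(np$pi0, 4),
            " > 1; falling back to central matching")
    np <- null_central_matching(mid, f_vals, z)
    null_method <- "central_matching"
  }
  delta0 <- np$delta0; sigma0 <- np$sigma0
  f0_vals <- stats::dnorm(mid, delta0, sigma0)
  pi0 <- np$pi0
  if (!is.finite(pi0)) {
    # theoretical route: match f to pi0 * f0 at the null center
    j <- which.min(abs(mid - delta0))
    pi0 <- f_vals[j] / f0_vals[j]
  }
  if (pi0 > 1 - 1e-4) {
    if (pi0 > 1) warning("pi0 estimate ", round(pi0, 4), " > 1; capped")
    pi0 <- 1 - 1e-4
  }
  pi0 <- max(pi0, 1e-4)
  f1_vals <- (f_vals - pi0 * f0_vals) / (1 - pi0)
  floored <- f1_vals < f1_floor
  f1_vals[floored] <- f1_floor
  structure(list(grid = grid, mid = mid, f0_vals = f0_vals, f_vals = f_vals,
                 f1_vals = f1_vals, f1_floored = floored, pi0 = pi0,
                 null_params = list(delta0 = delta0, sigma0 = sigma0),
                 null_method = null_method, n = n,
                 bins = bins, smooth_df = smooth_df),
            class = "MixtureFit")
}

# truncated-normal MLE for (delta0, sigma0, pi0) on a central window:
# center = median, half-width = 4.3 exp(-0.26 log10 N) robust SDs (the
# empirical-null literature's sample-size-adaptive window), wide enough to
# identify sigma yet anchored robustly against one-sided contamination.
null_mle <- function(z, central_frac = NULL) {
  med <- stats::median(z)
  s_rob <- diff(stats::quantile(z, c(0.25, 0.75), names = FALSE)) /
    (2 * stats::qnorm(0.75))
  bmult <- if (is.null(central_frac)) {
    4.3 * exp(-0.26 * log10(length(z)))
  } else {
    stats::qnorm(0.5 + central_frac / 2)
  }
  hw <- bmult * s_rob
  a <- med - hw; b <- med + hw
  z0 <- z[z >= a & z <= b]
  n0 <- length(z0)
  nll <- function(par) {
    d <- par[1L]; s <- exp(par[2L])
    mass <- stats::pnorm(b, d, s) - stats::pnorm(a, d, s)
    if (mass <= 0) return(1e10)
    -sum(stats::dnorm(z0, d, s, log = TRUE)) + n0 * log(mass)
  }
  fit <- stats::optim(c(mean(z0), log(stats::sd(z0))), nll,
                      method = "Nelder-Mead")
  delta0 <- fit$par[1L]; sigma0 <- exp(fit$par[2L])
  mass <- stats::pnorm(b, delta0, sigma0) - stats::pnorm(a, delta0, sigma0)
  list(delta0 = delta0, sigma0 = sigma0, pi0 = (n0 / length(z)) / mass)
}

# quadratic fit to log f around the central peak; vertex/curvature give
# (delta0, sigma0), the height gives pi0
null_central_matching <- function(mid, f_vals, z) {
  qs <- stats::quantile(z, c(0.25, 0.75), names = FALSE)
  sel <- mid >= qs[1L] & mid <= qs[2L] & f_vals > 0
  if (sum(sel) < 5L) stop("too few central bins for central matching")
  x <- mid[sel]; y <- log(f_vals[sel])
  co <- stats::coef(stats::lm(y ~ x + I(x^2)))
  if (!is.finite(co[3L]) || co[3L] >= 0) stop("central log-density not concave")
  sigma0 <- sqrt(-1 / (2 * co[3L]))
  delta0 <- co[2L] * sigma0^2
  peak <- co[1L] + co[2L] * delta0 + co[3L] * delta0^2
  pi0 <- exp(peak) * sqrt(2 * pi) * sigma0
  list(delta0 = delta0, sigma0 = sigma0, pi0 = pi0)
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf("MixtureFit (%s null): pi0 = %.4f, delta0 = %.4f, sigma0 = %.4f (n = %d)\n",
              x$null_method, x$pi0, x$null_params$delta0, x$null_params$sigma0, x$n))
  invisible(x)
}

# piecewise-linear interpolation on grid midpoints, flat beyond the ends
interp_density <- function(mid, vals, z) {
  stats::approx(mid, vals, xout = z, rule = 2)$y
}

#' Evaluate the fitted null density f0 at z
#' @param fit a `MixtureFit`.
#' @param z numeric vector.
#' @return density values.
#' @export
eval_f0 <- function(fit, z) stats::dnorm(z, fit$null_params$delta0,
                                         fit$null_params$sigma0)

#' Evaluate the fitted non-null density f1 at z
#' @param fit a `MixtureFit`.
#' @param z numeric vector.
#' @return density values (interpolated on the fit grid, flat extrapolation).
#' @export
eval_f1 <- function(fit, z) interp_density(fit$mid, fit$f1_vals, z)

#' Posterior null probability of a single site under the mixture
#'
#' `P(w = 0 | z) = (1 - p1) f0(z) / [(1 - p1) f0(z) + p1 f1(z)]`.
#'
#' @param fit a `MixtureFit`.
#' @param z numeric vector of z-scores.
#' @param prior_p1 prior probability of the non-null state, in (0, 1).
#' @return posterior null probabilities in \[0, 1\].
#' @export
site_null_posterior <- function(fit, z, prior_p1) {
  stopifnot(prior_p1 > 0, prior_p1 < 1)
  a0 <- (1 - prior_p1) * eval_f0(fit, z)
  a1 <- prior_p1 * eval_f1(fit, z)
  tot <- a0 + a1
  bad <- tot <= 0
  if (any(bad)) {
    warning("both densities zero at some z; returning prior null probability")
    a0[bad] <- 1 - prior_p1
    tot[bad] <- 1
  }
  a0 / tot
}

#' Initial DE configuration from the mixture fit
#'
#' A site starts differentially expressed when its posterior null probability
#' under the fitted mixture (prior non-null weight `1 - pi0`) falls below 0.5
#' — the Bayes classification boundary. Masked sites are excluded.
#'
#' @param fit a `MixtureFit` (fitted on the pooled observed z of `Z`).
#' @param Z an `EvidenceMatrix`.
#' @return binary vector over the observed sites, in site order (see
#'   [build_site_graph()]).
#' @export
initial_config <- function(fit, Z) {
  stopifnot(inherits(Z, "EvidenceMatrix"))
  z <- site_z_values(Z)
  p0 <- site_null_posterior(fit, z, prior_p1 = 1 - fit$pi0)
  as.integer(p0 < 0.5)
}

# observed-site z values in gene-major site order (see site_index())
site_z_values <- function(Z) {
  si <- site_index(Z)
  Z$z[cbind(si$g, si$c)]
}

#' Serialize a mixture fit as TSV
#'
#' Header line (as a comment) carries pi0/delta0/sigma0; body is a table of
#' (grid_mid, f0, f, f1).
#' @param fit a `MixtureFit`.
#' @param path output path.
#' @export
write_mixture <- function(fit, path) {
  hdr <- sprintf("# pi0=%.10g delta0=%.10g sigma0=%.10g null_method=%s n=%d",
                 fit$pi0, fit$null_params$delta0, fit$null_params$sigma0,
                 fit$null_method, fit$n)
  writeLines(hdr, path)
  dt <- data.table::data.table(grid_mid = fit$mid, f0 = fit$f0_vals,
                               f = fit$f_vals, f1 = fit$f1_vals)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}
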