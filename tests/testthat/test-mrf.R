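test_that("site graph wires gene and cell edges correctly", {
  z <- matrix(rnorm(6), 3, 2)
  lat <- make_lattice(z, gene_edges = rbind(c(1, 2), c(2, 3)),
                      cell_edges = rbind(c(1, 2)))
  g <- lat$graph
  expect_equal(g$n_sites, 6L)
  # gene-major order: sites are (g1,c1), (g1,c2), (g2,c1), ...
  expect_equal(g$sites$gene, rep(paste0("g", 1:3), each = 2))
  # gene edges never change the cell type; cell edges never change the gene
  for (e in seq_len(nrow(g$gene_edges))) {
    expect_equal(g$sites$cell_type[g$gene_edges[e, 1]],
                 g$sites$cell_type[g$gene_edges[e, 2]])
  }
  for (e in seq_len(nrow(g$cell_edges))) {
    expect_equal(g$sites$gene[g$cell_edges[e, 1]],
                 g$sites$gene[g$cell_edges[e, 2]])
  }
  # symmetry and no self-neighbors
  for (i in seq_len(g$n_sites)) {
    expect_false(i %in% g$gene_nb[[i]])
    for (j in g$gene_nb[[i]]) expect_true(i %in% g$gene_nb[[j]])
  }
  # masked sites are removed from the lattice
  z[2, 1] <- NA
  g2 <- make_lattice(z, gene_edges = rbind(c(1, 2)))$graph
  expect_equal(g2$n_sites, 5L)
  expect_error(make_lattice(matrix(NA_real_, 2, 2))$graph, "empty lattice")
})

test_that("neighbor sums count signed states", {
  # star around site 1 (gene 1, cell 1): gene-neighbors g2..g4 in cell 1
  z <- matrix(0, 4, 1)
  lat <- make_lattice(z, gene_edges = rbind(c(1, 2), c(1, 3), c(1, 4)))
  s <- neighbor_sums(lat$graph, c(9, 1, 1, 0), 1)  # w of site 1 irrelevant
  expect_equal(s$s_gene, 1)  # +1 +1 -1
  expect_equal(s$s_cell, 0)  # no cell edges

  lat2 <- make_lattice(matrix(0, 1, 5),
                       cell_edges = rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  s2 <- neighbor_sums(lat2$graph, c(1, 0, 0, 0, 0), 1)
  expect_equal(s2$s_cell, -4)
  s3 <- neighbor_sums(lat2$graph, c(0, 1, 1, 1, 1), 3)  # site 3 ~ only site 1
  expect_equal(s3$s_cell, -1)

  # no neighbors -> empty sums
  s4 <- neighbor_sums(make_lattice(matrix(0, 2, 1))$graph, c(1, 1), 1)
  expect_equal(c(s4$s_gene, s4$s_cell), c(0, 0))
})

test_that("conditional_prob is the logistic of the local field", {
  expect_equal(conditional_prob(mrf_params(0, 0, 0), 0, 0), 0.5)
  # reference-scale parameters (gamma -0.33, beta_gene 0.18, beta_cell 0.22)
  p <- mrf_params(-0.33, 0.18, 0.22)
  expect_equal(conditional_prob(p, 2, -1), 1 / (1 + exp(0.19)), tolerance = 1e-12)
  expect_equal(conditional_prob(p, 2, -1), 0.4526, tolerance = 1e-4)
  expect_equal(conditional_prob(p, 0, 0), 1 / (1 + exp(0.33)), tolerance = 1e-12)
  expect_equal(conditional_prob(p, 0, 0), 0.4182, tolerance = 1e-4)

  # complement identity, bounds, and monotone field effect
  for (s in -3:3) {
    pr <- conditional_prob(p, s, -s)
    expect_true(pr > 0 && pr < 1)
  }
  probs <- conditional_prob(mrf_params(0.1, 0.3, 0.2), -5:5, 0)
  expect_true(all(diff(probs) > 0))
  probs2 <- conditional_prob(mrf_params(0.1, 0.3, 0.2), 0, -5:5)
  expect_true(all(diff(probs2) > 0))
})

test_that("site_posterior applies the Bayes rule with the MRF prior", {
  # likelihood cancels when f0 = f1: posterior equals the prior conditional
  p <- mrf_params(-0.4, 0.3, 0.1)
  q <- site_posterior(flat_fit(), 0.3, p, 2, -1)
  expect_equal(q$q1, conditional_prob(p, 2, -1), tolerance = 1e-5)
  expect_equal(q$q0 + q$q1, 1)

  # with no field, a 3:1 likelihood ratio gives q1 = 0.75
  fit3 <- make_fit(f1_fun = function(x) 3 * dnorm(x), pi0 = 0.5)
  q3 <- site_posterior(fit3, 0, mrf_params(0, 0, 0), 0, 0)
  expect_equal(q3$q1, 0.75, tolerance = 1e-4)

  # zero non-null likelihood kills the state
  fit0 <- make_fit(f1_fun = function(x) ifelse(abs(x) < 1, 0, dnorm(x, 4)))
  expect_equal(site_posterior(fit0, 0, p, 1, 1)$q1, 0)
})

test_that("q_function scores the prior term and is maximized sensibly", {
  z <- matrix(c(0.2, -0.1, 0.4, 0.1), 2, 2)
  lat <- make_lattice(z)
  w <- c(0L, 1L, 0L, 1L)
  fit <- flat_fit()
  p0 <- mrf_params(0, 0, 0)
  # strongly negative gamma is penalized relative to gamma = 0
  expect_lt(q_function(fit, lat$Z, lat$graph, w, p0, mrf_params(-30, 0, 0)),
            q_function(fit, lat$Z, lat$graph, w, p0, p0))

  # single site, no neighbors, q1 = 0.5: 1-d scan peaks at gamma = 0
  lat1 <- make_lattice(matrix(0.0, 1, 1))
  gammas <- seq(-2, 2, by = 0.05)
  qs <- vapply(gammas, function(g)
    q_function(fit, lat1$Z, lat1$graph, 0L, p0, mrf_params(g, 0, 0)),
    numeric(1))
  expect_equal(gammas[which.max(qs)], 0, tolerance = 0.051)

  # definition identity: at params_free = params_post the value equals the
  # directly computed expected prior log-likelihood
  pp <- mrf_params(-0.5, 0.2, 0.1)
  s <- mrfDE:::all_neighbor_sums(lat$graph, w)
  qq <- site_posterior(fit, lat$graph$z, pp, s$s_gene, s$s_cell)
  Fv <- pp$gamma + pp$beta_gene * s$s_gene + pp$beta_cell * s$s_cell
  direct <- sum(qq$q1 * plogis(Fv, log.p = TRUE) +
                qq$q0 * plogis(-Fv, log.p = TRUE))
  expect_equal(q_function(fit, lat$Z, lat$graph, w, pp, pp), direct,
               tolerance = 1e-10)
})

test_that("m_step solves the weighted Bernoulli problem in closed form", {
  # no edges, flat likelihood, prior gamma = logit(0.3): every site has
  # q1 = 0.3 and zero neighbor sums, so the MLE is gamma = logit(0.3)
  lat <- make_lattice(matrix(rnorm(40), 20, 2))
  fit <- flat_fit()
  w <- rep(0L, 40)
  est <- m_step(fit, lat$Z, lat$graph, w, mrf_params(qlogis(0.3), 0, 0))
  expect_equal(est$gamma, qlogis(0.3), tolerance = 1e-3)
  expect_equal(est$beta_gene, 0)
  expect_equal(est$beta_cell, 0)

  # separation: q1 ~ 1 drives gamma to the box bound, flagged
  est2 <- m_step(fit, lat$Z, lat$graph, w, mrf_params(30, 0, 0))
  expect_equal(est2$gamma, 10, tolerance = 1e-6)
  expect_true(attr(est2, "at_bound")[1])
})

test_that("pseudo-likelihood estimation recovers a planted field", {
  set.seed(201)
  G <- 500L; C <- 18L
  gene_net <- gen_gene_network(G, 0.5)
  cell_net <- default_cell_network()
  truth_params <- mrf_params(-0.3, 0.2, 0.2)
  lat <- gen_latent_states(gene_net, cell_net, 0.4, truth_params, sweeps = 30)
  # fully informative evidence: z = 6 at DE sites, 0 elsewhere
  fit <- make_fit(f1_fun = function(x) dnorm(x, 6, 0.5), pi0 = 0.6)
  zm <- matrix(0, G, C, dimnames = list(gene_net$nodes, cell_net$nodes))
  zm[lat$w == 1L] <- 6
  Z <- evidence_matrix(zm, gene_net$nodes, cell_net$nodes)
  si <- mrfDE:::site_index(Z)
  w <- lat$w[cbind(si$g, si$c)]
  graph <- build_site_graph(Z, gene_net, cell_net)
  est <- m_step(fit, Z, graph, w, truth_params)
  expect_lt(abs(est$gamma - (-0.3)), 0.15)
  expect_lt(abs(est$beta_gene - 0.2), 0.15)
  expect_lt(abs(est$beta_cell - 0.2), 0.15)
})

test_that("each M-step ascends the Q function", {
  set.seed(202)
  z <- matrix(rnorm(60, sd = 1.5), 20, 3)
  lat <- make_lattice(z, gene_edges = cbind(1:19, 2:20),
                      cell_edges = rbind(c(1, 2), c(2, 3)))
  fit <- make_fit()
  w <- as.integer(runif(60) < 0.3)
  params <- mrf_params(0.5, 0.1, 0.4)
  for (k in 1:3) {
    new <- m_step(fit, lat$Z, lat$graph, w, params)
    expect_gte(q_function(fit, lat$Z, lat$graph, w, params, new),
               q_function(fit, lat$Z, lat$graph, w, params, params) - 1e-8)
    params <- new
  }
})

test_that("em_fit recovers a decoupled model's absence of coupling", {
  set.seed(203)
  hits <- 0L
  n_rep <- 12L
  for (r in seq_len(n_rep)) {
    G <- 150L; C <- 10L
    w <- as.integer(runif(G * C) < 0.3)
    z <- ifelse(w == 1, rnorm(G * C, 3), rnorm(G * C))
    lat <- make_lattice(matrix(z, G, C),
                        gene_edges = cbind(1:(G - 1), 2:G),
                        cell_edges = cbind(1:(C - 1), 2:C))
    fit <- make_fit(pi0 = 0.7)
    em <- em_fit(fit, lat$Z, lat$graph, max_iter = 40, seed = 300 + r)
    if (em$params$beta_gene <= 0.1 && em$params$beta_cell <= 0.1) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("em_fit converges and reports a trajectory", {
  set.seed(204)
  z <- matrix(c(rnorm(150), rnorm(50, 3))[sample(200)], 40, 5)
  lat <- make_lattice(z, gene_edges = cbind(1:39, 2:40))
  fit <- make_fit(pi0 = 0.75)
  em <- em_fit(fit, lat$Z, lat$graph, max_iter = 150, seed = 1)
  expect_true(is.matrix(em$trajectory))
  expect_equal(ncol(em$trajectory), 3L)
  expect_lte(em$n_iter, 150L)
  expect_length(em$w_tilde, lat$graph$n_sites)
})

test_that("gibbs matches the closed form when the field is off", {
  set.seed(205)
  z <- matrix(rnorm(400, sd = 1.6), 80, 5)
  lat <- make_lattice(z)  # no edges at all
  fit <- make_fit(pi0 = 0.7)
  gamma <- -0.6
  params <- mrf_params(gamma, 0, 0)
  post <- gibbs_posterior(fit, lat$Z, lat$graph, params,
                          n_iter = 50000, burn_in = 5000, seed = 9)
  f0 <- eval_f0(fit, lat$graph$z); f1 <- eval_f1(fit, lat$graph$z)
  s <- plogis(gamma)
  closed <- (1 - s) * f0 / ((1 - s) * f0 + s * f1)
  expect_lte(max(abs(post$p_null - closed)), 0.01)
})

test_that("two coupled sites agree with probability e/(1+e)", {
  # 1 gene x 2 cell types, one cell edge, gamma 0, beta_cell 1, f1 = f0:
  # exact enumeration gives P(w1 = w2) = 2e / (2e + 2)
  lat <- make_lattice(matrix(c(0.2, -0.3), 1, 2), cell_edges = rbind(c(1, 2)))
  fit <- flat_fit()
  params <- mrf_params(0, 0, 1)
  exact <- enumerate_exact(fit, lat$Z, lat$graph, params)
  expect_equal(exact, c(0.5, 0.5), tolerance = 1e-5)
  post <- gibbs_posterior(fit, lat$Z, lat$graph, params,
                          n_iter = 60000, burn_in = 10000, seed = 10)
  expect_lte(max(abs(post$p_null - 0.5)), 0.01)

  # agreement frequency from the same chain, via a two-state enumeration
  # identity: P(agree) = e/(1+e) when the marginals are 1/2
  expect_equal(exp(1) / (1 + exp(1)), 0.7311, tolerance = 1e-4)
})

test_that("gibbs is bitwise deterministic given the seed", {
  set.seed(206)
  z <- matrix(rnorm(30), 10, 3)
  lat <- make_lattice(z, gene_edges = cbind(1:9, 2:10))
  fit <- make_fit()
  params <- mrf_params(-0.3, 0.2, 0.2)
  p1 <- gibbs_posterior(fit, lat$Z, lat$graph, params, 2000, 500, seed = 77)
  p2 <- gibbs_posterior(fit, lat$Z, lat$graph, params, 2000, 500, seed = 77)
  expect_identical(p1$p_null, p2$p_null)
  p3 <- gibbs_posterior(fit, lat$Z, lat$graph, params, 2000, 500, seed = 78)
  expect_false(identical(p3$p_null, p1$p_null))
})

test_that("enumerate_exact refuses large lattices and handles one site", {
  lat1 <- make_lattice(matrix(0.0, 1, 1))
  expect_equal(enumerate_exact(flat_fit(), lat1$Z, lat1$graph,
                               mrf_params(0, 0, 0)), 0.5, tolerance = 1e-5)
  lat_big <- make_lattice(matrix(0, 7, 3))
  expect_error(enumerate_exact(flat_fit(), lat_big$Z, lat_big$graph,
                               mrf_params(0, 0, 0)), "refusing")
})

test_that("MRF parameter serialization round-trips", {
  f <- tmpfile(".txt")
  res <- list(params = mrf_params(-0.31, 0.18, 0.22), converged = TRUE,
              n_iter = 57L, seed = 3L)
  write_mrf_params(res, f, extra = list(alpha = 0.05))
  p <- read_mrf_params(f)
  expect_equal(p$gamma, -0.31)
  expect_equal(p$beta_gene, 0.18)
  expect_equal(p$beta_cell, 0.22)
})
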