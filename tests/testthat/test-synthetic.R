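test_that("sample_zinb has the stated moments", {
  set.seed(401)
  expect_true(all(sample_zinb(5, 2, 1, 1000) == 0))
  x <- sample_zinb(5, 2, 0.2, 1e5)
  expect_equal(mean(x), 4.0, tolerance = 0.1 / 4)  # E = (1 - pi) * mu
  y <- sample_zinb(3, 1e6, 0, 1e5)
  expect_equal(var(y), 3, tolerance = 0.05)  # Poisson limit
  # excess zeros beyond the NB component
  x2 <- sample_zinb(2, 1, 0.3, 1e5)
  nb0 <- (1 / 3)^1
  expect_gte(mean(x2 == 0), nb0)
  expect_equal(mean(x2 == 0), 0.3 + 0.7 * nb0, tolerance = 0.01)
  expect_error(sample_zinb(-1, 2, 0.1, 5), "mu")
  expect_error(sample_zinb(1, 0, 0.1, 5), "phi")
  expect_error(sample_zinb(1, 1, 1.5, 5), "pi_zero")
})

test_that("hyper-parameter draws have the hyper-law moments", {
  set.seed(402)
  h <- sim_hyper_params(mean_gamma = c(3, 1.5), disp_gamma = c(4, 2),
                        infl_beta = c(1, 1))
  d <- sample_celltype_params(h, 10000)
  expect_equal(mean(d$pi_zero), 0.5, tolerance = 0.02)
  expect_equal(mean(d$mu), 2, tolerance = 0.05)
  expect_equal(mean(d$phi), 2, tolerance = 0.05)
  expect_equal(nrow(sample_celltype_params(h, 0)), 0L)
})

test_that("gen_gene_network places edges only among selected genes", {
  set.seed(403)
  expect_equal(nrow(gen_gene_network(100, 0)$edges), 0L)

  net <- gen_gene_network(1000, 0.4)
  touched <- unique(as.vector(net$edges))
  expect_lte(length(touched), 400L)
  expect_equal(nrow(net$edges), round(400 * 4 / 2))

  full <- gen_gene_network(1000, 1, mean_degree = 4)
  expect_equal(nrow(full$edges), 2000L)
  expect_length(full$nodes, 1000L)
})

test_that("the packaged cell network is a connected 18-node graph", {
  net <- default_cell_network()
  expect_length(net$nodes, 18L)
  # breadth-first reachability from an arbitrary node
  reach <- net$nodes[1]
  repeat {
    nxt <- unique(c(reach, unlist(lapply(reach, neighbors, net = net))))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_setequal(reach, net$nodes)
  expect_error(default_cell_network(12), "18")

  # override file passes through read_edge_list
  f <- tmpfile()
  writeLines(c("X Y", "Y Z"), f)
  net2 <- default_cell_network(3, file = f)
  expect_equal(nrow(net2$edges), 2L)
})

test_that("latent states follow the coupling field", {
  set.seed(404)
  gene_net <- gen_gene_network(300, 0.5)
  cell_net <- default_cell_network()
  # absorbing near-zero flip probability keeps the all-null state
  w0 <- gen_latent_states(gene_net, cell_net, 0,
                         mrf_params(-10, 0, 0), sweeps = 5)
  expect_true(all(w0$w == 0L))

  # no coupling: i.i.d. Bernoulli(sigma(gamma)) marginals
  iso <- network_spec(paste0("g", 1:300), matrix(character(), 0, 2))
  iso_c <- network_spec(cell_net$nodes, matrix(character(), 0, 2))
  wb <- gen_latent_states(iso, iso_c, 0.5, mrf_params(qlogis(0.3), 0, 0),
                          sweeps = 3)
  expect_equal(mean(wb$w), 0.3, tolerance = 0.02)
  # chi-square goodness of fit against Bernoulli(0.3)
  n1 <- sum(wb$w); n <- length(wb$w)
  chi <- (n1 - 0.3 * n)^2 / (0.3 * n) + ((n - n1) - 0.7 * n)^2 / (0.7 * n)
  expect_lt(chi, qchisq(0.99, 1))

  # positive coupling raises edge agreement over the decoupled chain
  agree <- function(w, net) {
    e <- net$edges
    a <- w[e[, 1], , drop = FALSE] == w[e[, 2], , drop = FALSE]
    mean(a)
  }
  wc <- gen_latent_states(gene_net, cell_net, 0.3,
                          mrf_params(qlogis(0.3), 0.8, 0.8), sweeps = 10)
  wd <- gen_latent_states(gene_net, cell_net, 0.3,
                          mrf_params(qlogis(0.3), 0, 0), sweeps = 10)
  expect_gt(agree(wc$w, gene_net), agree(wd$w, gene_net))
})

test_that("simulate_dataset has the stated dimensions and fold changes", {
  set.seed(405)
  cfg <- sim_config(n_genes = 40, n_subjects_per_group = 3,
                    n_cells_per_type_per_subject = 8, eta = 0.5, kappa = 0.25,
                    lambda_fc = 2)
  sim <- simulate_dataset(cfg)
  expect_equal(dim(sim$data$counts), c(40L, 18L * 2L * 3L * 8L))
  expect_setequal(unique(sim$data$cell_meta$group), c("case", "control"))
  expect_equal(length(unique(sim$data$cell_meta$subject)), 6L)
  # tau is lambda or 1/lambda exactly at DE sites, 1 elsewhere
  expect_setequal(unique(sim$tau[sim$truth == 1L]), c(2, 0.5))
  expect_true(all(sim$tau[sim$truth == 0L] == 1))
})

test_that("under an all-null truth, case and control are identical in law", {
  set.seed(406)
  ok <- 0L
  for (r in 1:5) {
    cfg <- sim_config(n_genes = 30, n_subjects_per_group = 4,
                      n_cells_per_type_per_subject = 10, eta = 0.3, kappa = 0,
                      phi_sim = mrf_params(-10, 0, 0))
    sim <- simulate_dataset(cfg)
    expect_true(all(sim$truth == 0L))
    grp <- sim$data$cell_meta$group
    x <- as.vector(sim$data$counts[, grp == "case"])
    y <- as.vector(sim$data$counts[, grp == "control"])
    p <- suppressWarnings(ks.test(x, y)$p.value)
    if (p > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("realized fold changes concentrate near lambda at DE sites", {
  set.seed(407)
  cfg <- sim_config(n_genes = 60, n_subjects_per_group = 6,
                    n_cells_per_type_per_subject = 40, eta = 0.2, kappa = 0.3,
                    lambda_fc = 2)
  sim <- simulate_dataset(cfg)
  meta <- sim$data$cell_meta
  lfc <- c()
  for (ct in unique(meta$cell_type)) {
    ca <- Matrix::rowMeans(sim$data$counts[, meta$cell_type == ct & meta$group == "case", drop = FALSE])
    co <- Matrix::rowMeans(sim$data$counts[, meta$cell_type == ct & meta$group == "control", drop = FALSE])
    ci <- match(ct, colnames(sim$truth))
    de <- sim$truth[, ci] == 1L & ca > 0 & co > 0
    lfc <- c(lfc, abs(log2(ca[de] / co[de])))
  }
  expect_equal(median(lfc), 1, tolerance = 0.2)
})

test_that("normalization matches direct arithmetic and is compositional", {
  counts <- matrix(c(0L, 10000L, 5L, 5L), 2, 2)
  d <- make_dataset(counts, cell_type = "T", group = c("case", "control"))
  n <- normalize_log1p(d)
  expect_equal(n$counts[1, 1], 0)
  expect_equal(n$counts[2, 1], log(1 + 10000), tolerance = 1e-12)
  expect_equal(log(1 + 10001), 9.2104, tolerance = 1e-4)

  d2 <- make_dataset(counts * 2L, cell_type = "T", group = c("case", "control"))
  expect_equal(normalize_log1p(d2)$counts, n$counts)

  # zero-total cells are dropped with a warning
  counts3 <- cbind(counts, c(0L, 0L))
  d3 <- make_dataset(counts3, cell_type = "T",
                     group = c("case", "control", "case"))
  expect_warning(n3 <- normalize_log1p(d3), "zero-total")
  expect_equal(ncol(n3$counts), 2L)
})

test_that("QC removes cells outside the detected-gene and mito bounds", {
  set.seed(408)
  G <- 6000L
  detected <- c(100L, 300L, 5500L, 300L, 300L)
  counts <- matrix(0L, G, 5)
  for (j in 1:5) counts[seq_len(detected[j]), j] <- 1L
  genes <- c(paste0("MT-", 1:10), paste0("g", 1:(G - 10)))
  # cell 4: 6% mito counts; cell 5: 4%
  counts[1:10, 4] <- 0L; counts[1:2, 4] <- c(10L, 9L)   # 19 of ~309
  counts[1:10, 5] <- 0L; counts[1, 5] <- 12L            # 12 of ~302
  d <- expression_dataset(counts, genes, paste0("c", 1:5),
                          data.frame(cell_id = paste0("c", 1:5),
                                     cell_type = "T", subject = "s",
                                     group = c("case", "control", "case",
                                               "control", "case")))
  kept <- qc_filter_cells(d)
  expect_setequal(kept$cell_ids, c("c2", "c5"))

  # no mito genes: the mito rule is skipped with a warning
  d2 <- expression_dataset(counts, paste0("g", 1:G), paste0("c", 1:5),
                           d$cell_meta)
  expect_warning(k2 <- qc_filter_cells(d2), "skipped")
  expect_setequal(k2$cell_ids, c("c2", "c4", "c5"))
  expect_error(suppressWarnings(qc_filter_cells(d2, min_genes = 1e5)), "all cells")
})
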