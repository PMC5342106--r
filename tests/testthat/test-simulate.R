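test_that("config validation rejects infeasible settings", {
  expect_error(sim_config(n_genes = 10, n_modules = 3, module_size = 4),
               class = "netprog_config_error")
  expect_error(sim_config(p_in = 0.1, p_out = 0.5),
               class = "netprog_config_error")
  expect_error(sim_config(censoring_rate = 1),
               class = "netprog_config_error")
  expect_error(analysis_config(train_frac = 1),
               class = "netprog_config_error")
  expect_error(analysis_config(delta = -1),
               class = "netprog_config_error")
})

test_that("degenerate probabilities give exact cliques and nothing else", {
  cfg <- sim_config(n_genes = 20, n_modules = 2, module_size = 5,
                    p_in = 1, p_out = 0, seed = 11)
  pn <- simulate_network(cfg)
  g <- pn$network
  expect_equal(igraph::ecount(g), 2 * choose(5, 2))
  for (mod in pn$truth$module_members) {
    sub <- igraph::induced_subgraph(g, mod)
    expect_equal(igraph::ecount(sub), choose(5, 2))
  }
})

test_that("network generation is deterministic given the seed", {
  cfg <- sim_config(n_genes = 50, module_size = 6, seed = 42)
  e1 <- igraph::as_edgelist(simulate_network(cfg)$network)
  e2 <- igraph::as_edgelist(simulate_network(cfg)$network)
  expect_identical(e1, e2)
  ds1 <- simulate_omics(simulate_network(cfg), cfg)
  ds2 <- simulate_omics(simulate_network(cfg), cfg)
  expect_identical(ds1$mrna, ds2$mrna)
  expect_identical(ds1$clinical, ds2$clinical)
})

test_that("within-module edge density matches the binomial model", {
  # one module of 5 genes: 10 within-module pairs per replicate
  n_rep <- 400
  hits <- 0
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_genes = 15, n_modules = 1, module_size = 5,
                      p_in = 0.8, p_out = 0.01, seed = 1000 + r)
    pn <- simulate_network(cfg)
    sub <- igraph::induced_subgraph(pn$network, pn$truth$module_members[[1]])
    hits <- hits + igraph::ecount(sub)
  }
  n_pairs <- n_rep * choose(5, 2)
  se <- sqrt(n_pairs * 0.8 * 0.2)
  expect_lt(abs(hits - 0.8 * n_pairs), 3 * se)
})

test_that("zero censoring gives all events; target censoring is calibrated", {
  cfg0 <- sim_config(n_genes = 20, module_size = 4, n_patients = 100,
                     censoring_rate = 0, seed = 7)
  ds0 <- simulate_omics(simulate_network(cfg0), cfg0)
  expect_true(all(ds0$clinical$event == 1))

  cfg3 <- sim_config(n_genes = 20, module_size = 4, n_patients = 400,
                     censoring_rate = 0.3, seed = 7)
  ds3 <- simulate_omics(simulate_network(cfg3), cfg3)
  expect_lt(abs(mean(1 - ds3$clinical$event) - 0.3), 0.08)
})

test_that("methylation betas stay in [0, 1] and probes map to genes", {
  cfg <- sim_config(n_genes = 30, module_size = 4, n_patients = 50, seed = 9)
  ds <- simulate_omics(simulate_network(cfg), cfg)
  expect_true(all(ds$methylation >= 0 & ds$methylation <= 1))
  expect_setequal(unique(ds$probe_map$gene), rownames(ds$mrna))
  expect_setequal(ds$probe_map$probe, rownames(ds$methylation))
  probes_per_gene <- table(ds$probe_map$gene)
  expect_true(all(probes_per_gene >= 1 & probes_per_gene <= 3))
})

test_that("a planted univariate effect is recovered within its 95% CI", {
  # one active mRNA feature, log-HR 0.7 per SD, n = 400
  cfg <- sim_config(n_genes = 5, n_modules = 1, module_size = 2,
                    n_patients = 400, frac_active_features = 0,
                    censoring_rate = 0.2, seed = 1)
  net <- simulate_network(cfg)$network
  truth <- structure(list(
    module_members = list(module_1 = c("gene_1", "gene_2")),
    active_features = tibble::tibble(gene = "gene_1", modality = "mrna",
                                     log_hr = 0.7)),
    class = "planted_truth")
  covered <- 0
  for (r in 1:100) {
    cfg_r <- cfg; cfg_r$seed <- 5000 + r
    ds <- simulate_omics(net, cfg_r, truth)
    x <- as.numeric(scale(ds$mrna["gene_1", ]))
    fit <- survival::coxph(
      survival::Surv(ds$clinical$time, ds$clinical$event) ~ x)
    ci <- confint(fit)
    covered <- covered + (ci[1] <= 0.7 && 0.7 <= ci[2])
  }
  expect_gte(covered, 93)
})

test_that("empty truth yields a valid null dataset", {
  cfg <- sim_config(n_genes = 40, module_size = 4, n_patients = 120,
                    effect_log_hr = 0, seed = 13)
  pn <- simulate_network(cfg)
  expect_equal(nrow(pn$truth$active_features), 0)
  ds <- simulate_omics(pn, cfg)
  # screening p-values approximately uniform across features
  scr <- quietly(screen_features(ds, analysis_config(seed = 1)))
  p <- scr$p_lrt[scr$status == "ok"]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
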