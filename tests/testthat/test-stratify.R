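# fake evaluated models with controllable selection counts
mk_models <- function(ids, medians, features_per_model) {
  tb <- tibble::tibble(subnetwork = ids, size = 4L, median_c = medians,
                       permutation_p = 0.01,
                       passed = medians > 0.5, rank = seq_along(ids))
  details <- lapply(features_per_model, function(fs) {
    list(selection_counts = tibble::tibble(feature = fs,
                                           count = rep(10L, length(fs))))
  })
  names(details) <- ids
  attr(tb, "cv_results") <- details
  structure(tb, class = c("prognostic_models", class(tb)))
}

test_that("feature pooling unions selected features of C > 0.5 models", {
  cfg <- sim_config(n_genes = 20, module_size = 4, n_patients = 40,
                    probes_per_gene_max = 1, seed = 41)
  ds <- simulate_omics(simulate_network(cfg), cfg)
  meth_probe <- ds$probe_map$probe[1:2]
  models <- mk_models(
    c("s1", "s2", "s3"), c(0.7, 0.6, 0.5),
    list(c("mrna:gene_1", "cnv:gene_2", paste0("methylation:", meth_probe[1])),
         c("mrna:gene_1", "cnv:gene_3"),           # shared feature once
         c("mrna:gene_9")))                        # median 0.5: excluded
  pooled <- pool_features(models, ds, min_count = 5)
  expect_setequal(pooled$features,
                  c("cnv:gene_2", "cnv:gene_3", "mrna:gene_1",
                    paste0("methylation:", meth_probe[1])))
  expect_equal(sum(pooled$modality_counts$n), 4)
  expect_equal(dim(pooled$matrix), c(40, 4))

  none <- mk_models("s1", 0.4, list("mrna:gene_1"))
  expect_error(pool_features(none, ds), class = "netprog_stratify_error")
})

test_that("consensus NMF recovers planted patient blocks", {
  set.seed(42)
  n <- 60; p <- 12
  truth <- rep(1:2, each = n / 2)
  mat <- matrix(rnorm(n * p, sd = 0.4), n, p)
  mat[truth == 2, 1:6] <- mat[truth == 2, 1:6] + 3
  mat[truth == 1, 7:12] <- mat[truth == 1, 7:12] + 3
  rownames(mat) <- sprintf("p%02d", 1:n)
  res <- nmf_consensus(mat, k = 2, n_runs = 15, seed = 5)
  # adjusted agreement: labels match truth up to permutation
  agree <- max(mean(res$labels$cluster == truth),
               mean(res$labels$cluster == 3 - truth))
  expect_gte(agree, 0.9)
  # consensus is a valid co-clustering frequency matrix
  expect_true(isSymmetric(res$consensus))
  expect_true(all(diag(res$consensus) == 1))
  expect_true(all(res$consensus >= 0 & res$consensus <= 1))
  expect_true(all(abs(res$consensus * 15 - round(res$consensus * 15)) < 1e-9))

  # k-means oracle on the same matrix agrees
  km <- stats::kmeans(mat, centers = 2, nstart = 10)$cluster
  agree_km <- max(mean(res$labels$cluster == km),
                  mean(res$labels$cluster == 3 - km))
  expect_gte(agree_km, 0.9)
})

test_that("NMF consensus edge cases: single run, determinism, rank guard", {
  set.seed(43)
  mat <- matrix(runif(30 * 5), 30, dimnames = list(sprintf("p%02d", 1:30),
                                                   NULL))
  one <- nmf_consensus(mat, k = 2, n_runs = 1, seed = 2)
  expect_true(all(one$consensus %in% c(0, 1)))
  r1 <- nmf_consensus(mat, k = 2, n_runs = 5, seed = 9)
  r2 <- nmf_consensus(mat, k = 2, n_runs = 5, seed = 9)
  expect_identical(r1$labels, r2$labels)
  expect_error(nmf_consensus(mat, k = 5, n_runs = 5),
               class = "netprog_stratify_error")
  expect_error(nmf_consensus(mat, k = 1), class = "netprog_stratify_error")
})

test_that("strata with different hazards separate; labels are exchangeable", {
  set.seed(44)
  n <- 300
  cl <- rep(1:2, each = n / 2)
  sv <- sim_surv(ifelse(cl == 1, 0.8, -0.8), cens_frac = 0.2)
  labels <- tibble::tibble(patient_id = sprintf("p%03d", 1:n), cluster = cl)
  cmp <- compare_strata(labels, sv)
  expect_lt(cmp$logrank_p, 0.05)
  expect_gt(cmp$pairwise$hr[1], 1)  # cluster 1 is the poor-prognosis group

  # relabeling clusters leaves the log-rank statistic unchanged
  flipped <- labels
  flipped$cluster <- 3 - flipped$cluster
  cmp_f <- compare_strata(flipped, sv)
  expect_equal(cmp$logrank_p, cmp_f$logrank_p, tolerance = 1e-12)

  # permuted labels give HR near 1 on average
  set.seed(45)
  hrs <- replicate(30, {
    perm <- labels
    perm$cluster <- sample(perm$cluster)
    log(compare_strata(perm, sv)$pairwise$hr[1])
  })
  expect_lt(abs(mean(hrs)), 3 * sd(hrs) / sqrt(30) + 0.1)

  expect_error(compare_strata(tibble::tibble(patient_id = "x", cluster = 1),
                              sv[1, ]),
               class = "netprog_stratify_error")
})
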