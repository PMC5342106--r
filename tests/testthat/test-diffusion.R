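test_that("closed forms: beta = 1 gives identity; 2-node graph by hand", {
  g <- igraph::make_graph(~ a - b)
  F1 <- insulated_diffusion(g, beta = 1)
  expect_equal(unclass(F1)[, ], diag(2), ignore_attr = TRUE)

  F5 <- insulated_diffusion(g, beta = 0.5)
  expect_equal(unname(unclass(F5)[, ]),
               matrix(c(2 / 3, 1 / 3, 1 / 3, 2 / 3), 2), tolerance = 1e-12)

  expect_error(insulated_diffusion(g, beta = 0),
               class = "netprog_diffusion_error")
})

test_that("linear solve equals the dense inverse on random graphs", {
  set.seed(12)
  for (r in 1:50) {
    n <- sample(3:8, 1)
    g <- rand_graph(n, p = runif(1, 0.2, 0.7))
    beta <- runif(1, 0.1, 0.9)
    F_pkg <- insulated_diffusion(g, beta)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    deg <- colSums(A)
    W <- sweep(A, 2, pmax(deg, 1), "/")
    diag(W)[deg == 0] <- 1  # isolated nodes hold their heat
    F_dense <- beta * solve(diag(n) - (1 - beta) * W)
    expect_lt(max(abs(unclass(F_pkg)[, ] - F_dense)), 1e-10)
    expect_true(all(abs(colSums(F_pkg) - 1) < 1e-8))
  }
})

test_that("exchanged heat conserves the heat vector column-wise", {
  set.seed(13)
  g <- rand_graph(10, 0.3)
  F_mat <- insulated_diffusion(g, 0.4)
  h <- setNames(rexp(10), igraph::V(g)$name)
  E <- exchanged_heat(F_mat, h)
  expect_equal(colSums(E), h, tolerance = 1e-10)

  # all-zero heat -> zero matrix; single hot gene -> one nonzero column
  expect_true(all(exchanged_heat(F_mat, h * 0) == 0))
  h1 <- h * 0; h1[3] <- 5
  E1 <- exchanged_heat(F_mat, h1)
  expect_true(all(E1[, -3] == 0) && any(E1[, 3] > 0))

  expect_error(exchanged_heat(F_mat, h - 10),
               class = "netprog_diffusion_error")
})

test_that("strongly connected extraction matches the reachability oracle", {
  set.seed(14)
  for (r in 1:60) {
    n <- sample(4:8, 1)
    g <- rand_graph(n, 0.5)
    F_mat <- insulated_diffusion(g, 0.3)
    h <- setNames(rexp(n), igraph::V(g)$name)
    E <- exchanged_heat(F_mat, h)
    delta <- stats::quantile(E[E > 0], 0.6, names = FALSE)
    subs <- extract_subnetworks(E, delta, min_size = 2)
    # oracle: SCCs of arcs j -> i iff E_ij > delta
    adj <- t(E > delta); diag(adj) <- FALSE
    comp <- brute_scc(adj)
    oracle_sets <- unname(Filter(function(s) length(s) >= 2,
                                 split(colnames(E), comp)))
    got_sets <- lapply(subs$genes, sort)
    expect_setequal(lapply(oracle_sets, sort), got_sets)
  }
})

test_that("subnetworks shrink weakly as delta grows", {
  set.seed(15)
  g <- rand_graph(12, 0.35)
  F_mat <- insulated_diffusion(g, 0.4)
  h <- setNames(rexp(12), igraph::V(g)$name)
  E <- exchanged_heat(F_mat, h)
  deltas <- stats::quantile(E[E > 0], c(0.3, 0.5, 0.7, 0.9), names = FALSE)
  prev <- NULL
  for (d in deltas) {
    subs <- extract_subnetworks(E, d, min_size = 2)
    sets <- subs$genes
    if (!is.null(prev)) {
      # every SCC at the larger delta sits inside an SCC at the smaller one
      for (s in sets) {
        expect_true(any(vapply(prev, function(p) all(s %in% p), logical(1))))
      }
    }
    prev <- sets
  }
})

test_that("delta extremes behave as documented", {
  set.seed(16)
  g <- rand_graph(8, 0.5)
  F_mat <- insulated_diffusion(g, 0.4)
  h <- setNames(rexp(8), igraph::V(g)$name)
  E <- exchanged_heat(F_mat, h)
  expect_equal(nrow(extract_subnetworks(E, max(E) + 1, min_size = 2)), 0)
  expect_equal(nrow(extract_subnetworks(E, min(E[E > 0]) / 2,
                                        min_size = 100)), 0)
})

test_that("automatic delta selection is calibrated and guarded", {
  # all-equal positive entries with cap 2: delta must equal that entry
  n <- 6
  E_const <- matrix(0.25, n, n,
                    dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  expect_equal(auto_delta(rep(list(E_const), 10), max_size_cap = 2), 0.25)

  expect_error(auto_delta(rep(list(E_const), 10), max_size_cap = Inf),
               class = "netprog_diffusion_error")
  expect_error(auto_delta(rep(list(E_const), 5)),
               class = "netprog_diffusion_error")
  expect_error(auto_delta(rep(list(E_const * 0), 10), max_size_cap = 5),
               class = "netprog_diffusion_error")

  # larger cap -> smaller or equal delta
  set.seed(17)
  g <- rand_graph(15, 0.3)
  F_mat <- insulated_diffusion(g, 0.4)
  Es <- lapply(1:10, function(i) {
    exchanged_heat(F_mat, setNames(rexp(15), igraph::V(g)$name))
  })
  d_small <- auto_delta(Es, max_size_cap = 3)
  d_large <- auto_delta(Es, max_size_cap = 8)
  expect_lte(d_large, d_small)
})
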