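# Brute-force oracles and small simulation helpers shared across tests.
# Every oracle here is written independently of the package's own code
# paths: pair enumeration by double loop, reachability by matrix powers,
# log-rank by the direct observed-minus-expected tabulation.

# Harrell's C by explicit double loop over ordered pairs.
brute_concordance <- function(risk, time, event) {
  n <- length(risk)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      permissible <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (!permissible) next
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Strongly connected components of a directed adjacency matrix via
# reachability (boolean matrix powers): i ~ j iff i reaches j and j reaches i.
brute_scc <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach > 0)
  }
  comp <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    next_id <- next_id + 1L
    members <- which(reach[i, ] & reach[, i])
    comp[members] <- next_id
  }
  comp
}

# Log-rank chi-square by direct observed/expected tabulation (two groups).
brute_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in times) {
    at_risk <- time >= t
    n_total <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_total <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d_total * n1 / n_total
    if (n_total > 1) {
      v <- v + d_total * (n1 / n_total) * (1 - n1 / n_total) *
        (n_total - d_total) / (n_total - 1)
    }
  }
  (o1 - e1)^2 / v
}

# Weibull proportional-hazards survival draw for a given linear predictor.
sim_surv <- function(eta, shape = 1.2, scale = 5, cens_frac = 0) {
  n <- length(eta)
  t_event <- scale * (-log(runif(n)) * exp(-eta))^(1 / shape)
  if (cens_frac == 0) {
    return(data.frame(time = t_event, event = 1L))
  }
  f <- function(r) mean(1 - exp(-r * t_event)) - cens_frac
  rate <- uniroot(f, c(1e-8, 1e8), tol = 1e-10)$root
  c_time <- rexp(n, rate)
  data.frame(time = pmin(t_event, c_time),
             event = as.integer(t_event <= c_time))
}

# Random simple undirected graph on n nodes as an igraph with names.
rand_graph <- function(n, p = 0.4) {
  a <- matrix(runif(n * n) < p, n, n)
  a[lower.tri(a, diag = TRUE)] <- FALSE
  a <- a | t(a)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  igraph::V(g)$name <- paste0("g", seq_len(n))
  g
}

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

# A small evaluated cohort reused by risk/stratification tests.
small_eval_fixture <- function() {
  cfg <- sim_config(n_genes = 60, n_modules = 1, module_size = 6,
                    n_patients = 150, effect_log_hr = 1.0, seed = 5)
  sim <- simulate_cohort(cfg)
  acfg <- analysis_config(n_cv_splits = 10, n_permutations = 20,
                          n_perm_splits = 5, n_discovery_perms = 20,
                          n_delta_perms = 10, nmf_runs = 10, nlambda = 30,
                          seed = 3)
  screened <- quietly(collapse_methylation(screen_features(sim$dataset, acfg)))
  list(sim = sim, acfg = acfg, screened = screened)
}
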