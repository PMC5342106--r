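# Synthetic cohorts: planted-module networks and matched multi-omic +
# survival data. The generator draws a sparse background interactome with
# dense planted modules, then survival times from a Weibull
# proportional-hazards model whose linear predictor loads on the planted
# features, with independent exponential censoring calibrated to a target
# censoring fraction.

#' Generate a random interactome with planted dense modules
#'
#' Nodes are `gene_1 ... gene_N`. Disjoint planted modules of `module_size`
#' genes get within-module edges with probability `p_in`; all remaining pairs
#' get background edges with probability `p_out`. The result is a simple
#' undirected graph with no self-loops, reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a list with `network` (an `igraph` graph with vertex names) and
#'   `truth` (a `planted_truth`: module memberships, active (gene, modality)
#'   features, and their true log hazard ratios).
#' @export
#' @examples
#' net <- simulate_network(sim_config(n_genes = 40, module_size = 5, seed = 2))
#' igraph::vcount(net$network)
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- paste0("gene_", seq_len(cfg$n_genes))
  modules <- split(
    genes[seq_len(cfg$n_modules * cfg$module_size)],
    rep(seq_len(cfg$n_modules), each = cfg$module_size)
  )
  names(modules) <- paste0("module_", seq_along(modules))

  edges <- with_substream(cfg$seed, "network", {
    idx <- which(upper.tri(matrix(0, cfg$n_genes, cfg$n_genes)), arr.ind = TRUE)
    module_of <- rep(NA_integer_, cfg$n_genes)
    for (m in seq_along(modules)) {
      module_of[match(modules[[m]], genes)] <- m
    }
    m1 <- module_of[idx[, 1]]; m2 <- module_of[idx[, 2]]
    same_module <- !is.na(m1) & !is.na(m2) & m1 == m2
    p <- ifelse(same_module, cfg$p_in, cfg$p_out)
    keep <- runif(nrow(idx)) < p
    cbind(genes[idx[keep, 1]], genes[idx[keep, 2]])
  })

  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE)
  )

  truth <- with_substream(cfg$seed, "truth", {
    module_genes <- unlist(modules, use.names = FALSE)
    grid <- expand.grid(gene = module_genes,
                        modality = c("mrna", "cnv", "methylation"),
                        stringsAsFactors = FALSE)
    active <- grid[runif(nrow(grid)) < cfg$frac_active_features, , drop = FALSE]
    tibble(
      gene = active$gene, modality = active$modality,
      log_hr = rep(cfg$effect_log_hr, nrow(active))
    )
  })
  truth <- truth[truth$log_hr != 0, , drop = FALSE]

  structure(
    list(network = g,
         truth = structure(list(module_members = modules,
                                active_features = truth),
                           class = "planted_truth")),
    class = "planted_network"
  )
}

#' Generate multi-omic feature matrices and survival outcomes
#'
#' Per-patient features are drawn i.i.d.: mRNA and CNV as Gaussian scores,
#' methylation as a logistic transform of a gene-level Gaussian latent (so
#' beta-values stay in `[0, 1]`) observed through 1 to
#' `cfg$probes_per_gene_max` noisy probes per gene. The linear predictor is
#' the sum of true log hazard ratios times the standardized active features
#' (the methylation effect acts on the latent scale). Survival times follow a
#' Weibull proportional-hazards model; censoring is independent exponential
#' with its rate solved numerically so the realized censoring fraction
#' approximates `cfg$censoring_rate`. Clinical covariates (age, stage, lymph
#' node count, tumor weight) are generated independently of survival.
#'
#' @param net a `planted_network` from [simulate_network()], or its
#'   `network` element together with `truth`.
#' @param truth optional `planted_truth`; defaults to `net$truth`.
#' @param cfg the [sim_config()] used for `net`.
#' @return an `omics_dataset`: matrices `mrna`, `cnv` (gene x patient),
#'   `methylation` (probe x patient), a `probe_map` tibble, and a `clinical`
#'   tibble with `patient_id`, `age`, `stage`, `lymph_node_count`,
#'   `tumor_weight`, `time`, `event`.
#' @export
simulate_omics <- function(net, cfg, truth = NULL) {
  if (inherits(net, "planted_network")) {
    if (is.null(truth)) truth <- net$truth
    net <- net$network
  }
  stopifnot(inherits(cfg, "sim_config"))
  genes <- igraph::V(net)$name
  n <- cfg$n_patients
  patients <- sprintf("patient_%03d", seq_len(n))

  dat <- with_substream(cfg$seed, "omics", {
    mrna <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                   dimnames = list(genes, patients))
    cnv <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                  dimnames = list(genes, patients))
    meth_latent <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                          dimnames = list(genes, patients))
    n_probes <- sample.int(cfg$probes_per_gene_max, length(genes),
                           replace = TRUE)
    probe_map <- tibble(
      probe = unlist(lapply(seq_along(genes), function(i) {
        paste0("cg_", genes[i], "_", seq_len(n_probes[i]))
      })),
      gene = rep(genes, n_probes)
    )
    meth <- meth_latent[probe_map$gene, , drop = FALSE] +
      matrix(rnorm(nrow(probe_map) * n, sd = 0.3), nrow = nrow(probe_map))
    meth <- plogis(meth)
    rownames(meth) <- probe_map$probe
    list(mrna = mrna, cnv = cnv, meth = meth, meth_latent = meth_latent,
         probe_map = probe_map)
  })

  # Linear predictor over standardized active features; the methylation
  # effect is specified on the latent (pre-logistic) scale.
  active <- if (is.null(truth)) tibble(gene = character(), modality = character(),
                                       log_hr = numeric()) else truth$active_features
  eta <- rep(0, n)
  if (nrow(active) > 0) {
    for (i in seq_len(nrow(active))) {
      src <- switch(active$modality[i],
                    mrna = dat$mrna, cnv = dat$cnv,
                    methylation = dat$meth_latent)
      x <- src[active$gene[i], ]
      eta <- eta + active$log_hr[i] * as.numeric(scale(x))
    }
  }

  surv <- with_substream(cfg$seed, "survival", {
    u <- runif(n)
    t_event <- cfg$baseline_scale *
      (-log(u) * exp(-eta))^(1 / cfg$baseline_shape)
    if (cfg$censoring_rate == 0) {
      list(time = t_event, event = rep(1L, n))
    } else {
      # Expected censoring fraction for Exp(rate) censoring given the
      # realized event times: mean P(C < T_i) = mean(1 - exp(-rate T_i)).
      frac <- function(rate) mean(1 - exp(-rate * t_event)) - cfg$censoring_rate
      rate <- uniroot(frac, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
      c_time <- rexp(n, rate = rate)
      list(time = pmin(t_event, c_time),
           event = as.integer(t_event <= c_time))
    }
  })

  clinical <- with_substream(cfg$seed, "clinical", {
    tibble(
      patient_id = patients,
      age = round(rnorm(n, 56, 11), 1),
      stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                     prob = c(0.15, 0.45, 0.3, 0.1)),
      lymph_node_count = rpois(n, 3),
      tumor_weight = round(rlnorm(n, log(30), 0.5), 1)
    )
  })
  clinical$time <- surv$time
  clinical$event <- surv$event

  structure(
    list(mrna = dat$mrna, cnv = dat$cnv, methylation = dat$meth,
         probe_map = dat$probe_map, clinical = clinical),
    class = "omics_dataset"
  )
}

#' Generate a complete synthetic cohort in one call
#'
#' Convenience wrapper chaining [simulate_network()] and [simulate_omics()].
#'
#' @param cfg a [sim_config()].
#' @return a list with `network`, `truth`, and `dataset`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_genes = 40, module_size = 5,
#'                                   n_patients = 60, seed = 3))
#' dim(sim$dataset$mrna)
simulate_cohort <- function(cfg) {
  pn <- simulate_network(cfg)
  ds <- simulate_omics(pn, cfg)
  list(network = pn$network, truth = pn$truth, dataset = ds)
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("<omics_dataset>\n")
  cat("  patients:    ", nrow(x$clinical), "\n")
  cat("  mRNA genes:  ", nrow(x$mrna), "\n")
  cat("  CNV genes:   ", nrow(x$cnv), "\n")
  cat("  meth probes: ", nrow(x$methylation),
      " (", length(unique(x$probe_map$gene)), " genes )\n")
  cat("  events:      ", sum(x$clinical$event), "/", nrow(x$clinical), "\n")
  invisible(x)
}
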