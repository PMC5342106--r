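# Configuration objects and deterministic seed substreams.

#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the synthetic-data module: the
#' planted-module network model, the per-modality effect sizes entering the
#' proportional-hazards generator, and the censoring target. Defaults describe
#' a cohort of modest size with a clearly prognostic planted module, the
#' regime the pipeline is designed to detect.
#'
#' @param n_genes total number of genes (network nodes).
#' @param n_modules number of planted modules.
#' @param module_size genes per planted module (modules are disjoint).
#' @param p_in within-module edge probability.
#' @param p_out background edge probability (must be < `p_in`).
#' @param n_patients cohort size.
#' @param effect_log_hr log hazard ratio per SD of an active feature.
#' @param frac_active_features fraction of planted-module gene/modality
#'   features that carry a true effect.
#' @param baseline_scale,baseline_shape Weibull baseline-hazard scale (time
#'   units) and shape of the survival generator.
#' @param censoring_rate target fraction of censored patients in `[0, 1)`.
#' @param probes_per_gene_max maximum methylation probes per gene (probes are
#'   drawn uniformly on `1:probes_per_gene_max`).
#' @param seed master seed; all generator stages consume derived substreams.
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, module_size = 5, n_patients = 60, seed = 1)
#' cfg$p_in
sim_config <- function(n_genes = 300,
                       n_modules = 1,
                       module_size = 8,
                       p_in = 0.8,
                       p_out = 0.01,
                       n_patients = 400,
                       effect_log_hr = 0.7,
                       frac_active_features = 1,
                       baseline_scale = 5,
                       baseline_shape = 1.2,
                       censoring_rate = 0.3,
                       probes_per_gene_max = 3,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size), p_in = p_in, p_out = p_out,
    n_patients = as.integer(n_patients), effect_log_hr = effect_log_hr,
    frac_active_features = frac_active_features,
    baseline_scale = baseline_scale, baseline_shape = baseline_shape,
    censoring_rate = censoring_rate,
    probes_per_gene_max = as.integer(probes_per_gene_max),
    seed = as.integer(seed)
  )
  if (cfg$n_modules * cfg$module_size > cfg$n_genes) {
    abort("infeasible config: n_modules * module_size exceeds n_genes",
          class = "netprog_config_error")
  }
  if (!(p_in >= 0 && p_in <= 1 && p_out >= 0 && p_out <= 1)) {
    abort("p_in and p_out must lie in [0, 1]", class = "netprog_config_error")
  }
  if (p_in <= p_out) {
    abort("p_in must exceed p_out (planted modules must be denser than background)",
          class = "netprog_config_error")
  }
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("censoring_rate must lie in [0, 1)", class = "netprog_config_error")
  }
  if (baseline_shape <= 0 || baseline_scale <= 0) {
    abort("Weibull baseline shape and scale must be positive",
          class = "netprog_config_error")
  }
  if (frac_active_features < 0 || frac_active_features > 1) {
    abort("frac_active_features must lie in [0, 1]",
          class = "netprog_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Analysis configuration for the discovery/evaluation pipeline
#'
#' Holds every tunable of the downstream pipeline, with defaults matching the
#' reference procedure: raw `p < 0.05` screening, restart probability 0.4 for
#' the insulated diffusion, subnetworks of at least 4 genes, 100 Monte-Carlo
#' 80/20 splits, 100 survival permutations, elastic-net mixing 0.5, stability
#' cutoff "selected more than 5 times", and two NMF strata.
#'
#' @param alpha_screen per-feature screening significance cutoff.
#' @param beta_restart diffusion restart probability in `(0, 1]`.
#' @param delta exchanged-heat threshold, or `"auto"` for the
#'   permutation-calibrated choice (see [auto_delta()]).
#' @param min_subnetwork_size smallest reported subnetwork.
#' @param n_cv_splits Monte-Carlo cross-validation splits.
#' @param train_frac training fraction per split.
#' @param n_permutations survival permutations for model significance.
#' @param n_perm_splits CV splits used inside each permutation (a reduced
#'   budget; set equal to `n_cv_splits` for full fidelity).
#' @param enet_mix elastic-net mixing parameter (`alpha` in glmnet terms).
#' @param nlambda length of the regularization path.
#' @param lambda_nfolds folds of the inner partial-likelihood CV choosing the
#'   penalty strength.
#' @param stability_min_count a feature enters the final model only if
#'   selected strictly more than this many times across splits.
#' @param nmf_k number of NMF strata.
#' @param nmf_runs NMF restarts entering the consensus matrix.
#' @param n_discovery_perms heat permutations used by the subnetwork
#'   significance test.
#' @param n_delta_perms heat permutations used by the automatic delta choice.
#' @param delta_size_cap largest-component cap targeted by the automatic
#'   delta choice; the default 3 keeps chance components under permuted
#'   heats below even a triad, so that every reportable subnetwork
#'   (`min_subnetwork_size` or larger) is impossible by chance at the
#'   chosen threshold.
#' @param seed master seed for every randomized stage.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(alpha_screen = 0.05,
                            beta_restart = 0.4,
                            delta = "auto",
                            min_subnetwork_size = 4,
                            n_cv_splits = 100,
                            train_frac = 0.8,
                            n_permutations = 100,
                            n_perm_splits = 20,
                            enet_mix = 0.5,
                            nlambda = 50,
                            lambda_nfolds = 5,
                            stability_min_count = 5,
                            nmf_k = 2,
                            nmf_runs = 50,
                            n_discovery_perms = 100,
                            n_delta_perms = 20,
                            delta_size_cap = 3,
                            seed = 1L) {
  cfg <- list(
    alpha_screen = alpha_screen, beta_restart = beta_restart, delta = delta,
    min_subnetwork_size = as.integer(min_subnetwork_size),
    n_cv_splits = as.integer(n_cv_splits), train_frac = train_frac,
    n_permutations = as.integer(n_permutations),
    n_perm_splits = as.integer(n_perm_splits),
    enet_mix = enet_mix, nlambda = as.integer(nlambda),
    lambda_nfolds = as.integer(lambda_nfolds),
    stability_min_count = as.integer(stability_min_count),
    nmf_k = as.integer(nmf_k), nmf_runs = as.integer(nmf_runs),
    n_discovery_perms = as.integer(n_discovery_perms),
    n_delta_perms = as.integer(n_delta_perms),
    delta_size_cap = as.integer(delta_size_cap),
    seed = as.integer(seed)
  )
  counts <- c("min_subnetwork_size", "n_cv_splits", "n_permutations",
              "n_perm_splits", "nlambda", "lambda_nfolds", "nmf_k",
              "nmf_runs", "n_discovery_perms", "n_delta_perms",
              "delta_size_cap")
  if (any(unlist(cfg[counts]) < 1)) {
    abort("all count parameters must be >= 1", class = "netprog_config_error")
  }
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1) {
    abort("train_frac must lie in (0, 1)", class = "netprog_config_error")
  }
  if (cfg$alpha_screen <= 0 || cfg$alpha_screen > 1) {
    abort("alpha_screen must lie in (0, 1]", class = "netprog_config_error")
  }
  if (cfg$beta_restart <= 0 || cfg$beta_restart > 1) {
    abort("beta_restart must lie in (0, 1]", class = "netprog_config_error")
  }
  if (!identical(cfg$delta, "auto") &&
      (!is.numeric(cfg$delta) || cfg$delta <= 0)) {
    abort("delta must be \"auto\" or a positive number",
          class = "netprog_config_error")
  }
  if (cfg$enet_mix < 0 || cfg$enet_mix > 1) {
    abort("enet_mix must lie in [0, 1]", class = "netprog_config_error")
  }
  if (cfg$stability_min_count < 0) {
    abort("stability_min_count must be >= 0", class = "netprog_config_error")
  }
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file with keys mirroring [analysis_config()] arguments.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
          class = "netprog_config_error")
  }
  do.call(analysis_config, vals)
}

#' Read a simulation configuration from a YAML file
#' @param path YAML file with keys mirroring [sim_config()] arguments.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
          class = "netprog_config_error")
  }
  do.call(sim_config, vals)
}

# Derive a named substream seed from a master seed. Stage labels keep the
# generator stages independent; `rep` indexes replicates within a stage.
# The map is a fixed LCG-style hash kept strictly below 2^31 - 1.
substream_seed <- function(seed, label, rep = 0L) {
  chars <- utf8ToInt(label)
  h <- sum(chars * seq_along(chars)) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                h * 9973 + as.numeric(rep) * 7919) %% 2147483647)
}

# Evaluate `expr` under a derived substream without disturbing the caller's
# RNG state.
with_substream <- function(seed, label, expr, rep = 0L) {
  withr::with_seed(substream_seed(seed, label, rep), expr)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(" ", nm, "=", format(x[[nm]]), "\n")
  invisible(x)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(" ", nm, "=", format(x[[nm]]), "\n")
  invisible(x)
}
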