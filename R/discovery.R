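# Subnetwork discovery: diffusion + thresholding + permutation significance.
# Significance follows the size-class logic: permuting the heats over the
# network genes preserves the topology and the heat distribution but breaks
# their association, so the number of hot components of each size under
# permutation calibrates how surprising the observed components are.

#' Size-class significance of discovered subnetworks
#'
#' Permutes the heat scores uniformly over the network genes `n_perm` times
#' and, for each observed size class `s`, computes the add-one empirical
#' p-value of seeing at least as many components of size >= `s` as observed:
#' `p(s) = (#perms with count >= observed + 1) / (n_perm + 1)`.
#'
#' @param F_mat diffusion matrix of the network.
#' @param heats named heat vector (or `gene_heat` tibble).
#' @param subnetworks a `subnetwork_set` from [extract_subnetworks()].
#' @param n_perm number of heat permutations (>= 20).
#' @param delta,min_size threshold and size floor used for the observed
#'   extraction (defaults taken from `subnetworks` attributes).
#' @param seed RNG seed for the permutations.
#' @return the `subnetwork_set` with a `size_class_p` column added.
#' @export
discovery_significance <- function(F_mat, heats, subnetworks, n_perm = 100,
                                   delta = attr(subnetworks, "delta"),
                                   min_size = attr(subnetworks, "min_size"),
                                   seed = 1L) {
  if (n_perm < 20) {
    abort("n_perm must be >= 20", class = "netprog_discovery_error")
  }
  if (nrow(subnetworks) == 0) {
    subnetworks$size_class_p <- numeric(0)
    return(subnetworks)
  }
  if (inherits(heats, "gene_heat") || is.data.frame(heats)) {
    heats <- setNames(heats$score, heats$gene)
  }
  genes <- colnames(F_mat)
  h <- setNames(rep(0, length(genes)), genes)
  common <- intersect(names(heats), genes)
  h[common] <- heats[common]

  sizes_per_perm <- with_substream(seed, "discovery-perm", {
    lapply(seq_len(n_perm), function(p) {
      hp <- setNames(sample(h), genes)
      Ep <- sweep(F_mat, 2, hp, "*")
      sub <- extract_subnetworks(Ep, delta, min_size)
      sub$size
    })
  })
  obs_sizes <- subnetworks$size
  size_classes <- sort(unique(obs_sizes))
  p_of_class <- vapply(size_classes, function(s) {
    obs_count <- sum(obs_sizes >= s)
    hits <- vapply(sizes_per_perm, function(sz) sum(sz >= s) >= obs_count,
                   logical(1))
    (sum(hits) + 1) / (n_perm + 1)
  }, numeric(1))
  subnetworks$size_class_p <- p_of_class[match(obs_sizes, size_classes)]
  subnetworks
}

#' Discover survival-linked subnetworks on an interactome
#'
#' End-to-end discovery stage: insulated diffusion with restart
#' `cfg$beta_restart`, exchanged-heat computation, threshold selection
#' (`cfg$delta`, or the permutation-calibrated automatic choice), strongly
#' connected component extraction at `cfg$min_subnetwork_size`, and
#' size-class permutation significance.
#'
#' @param net the interactome (`igraph`, vertex names are gene symbols).
#' @param heats a `gene_heat` tibble or named heat vector.
#' @param cfg an [analysis_config()].
#' @return a `subnetwork_set` tibble with `size_class_p`, plus attributes
#'   `delta`, `beta`, and `F` (the diffusion matrix).
#' @export
discover_subnetworks <- function(net, heats, cfg = analysis_config()) {
  if (inherits(heats, "gene_heat") || is.data.frame(heats)) {
    heats <- setNames(heats$score, heats$gene)
  }
  F_mat <- insulated_diffusion(net, cfg$beta_restart)
  E <- exchanged_heat(F_mat, heats)
  h <- attr(E, "heat")
  delta <- cfg$delta
  if (identical(delta, "auto")) {
    E_perm <- with_substream(cfg$seed, "delta-perm", {
      lapply(seq_len(max(10L, cfg$n_delta_perms)), function(p) {
        hp <- setNames(sample(h), names(h))
        sweep(F_mat, 2, hp, "*")
      })
    })
    delta <- auto_delta(E_perm, cfg$delta_size_cap)
  }
  subs <- extract_subnetworks(E, delta, cfg$min_subnetwork_size, net = net)
  subs <- discovery_significance(F_mat, h, subs,
                                 n_perm = cfg$n_discovery_perms,
                                 delta = delta,
                                 min_size = cfg$min_subnetwork_size,
                                 seed = cfg$seed)
  attr(subs, "beta") <- cfg$beta_restart
  attr(subs, "F") <- F_mat
  subs
}

#' Cross-network subnetwork sharing by gene overlap
#'
#' Reports pairs of subnetworks from two discovery runs whose gene sets have
#' Jaccard index at or above `threshold`.
#'
#' @param subs_a,subs_b `subnetwork_set` tibbles, typically from different
#'   interactomes.
#' @param threshold minimum Jaccard index (default 0.5).
#' @return a tibble: `id_a`, `id_b`, `jaccard`.
#' @export
subnetwork_overlap <- function(subs_a, subs_b, threshold = 0.5) {
  if (nrow(subs_a) == 0 || nrow(subs_b) == 0) {
    return(tibble(id_a = character(), id_b = character(), jaccard = numeric()))
  }
  grid <- expand.grid(i = seq_len(nrow(subs_a)), j = seq_len(nrow(subs_b)))
  jac <- vapply(seq_len(nrow(grid)), function(r) {
    a <- subs_a$genes[[grid$i[r]]]
    b <- subs_b$genes[[grid$j[r]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  out <- tibble(id_a = subs_a$id[grid$i], id_b = subs_b$id[grid$j],
                jaccard = jac)
  out[out$jaccard >= threshold, , drop = FALSE]
}

#' @export
print.subnetwork_set <- function(x, ...) {
  cat("<subnetwork_set> ", nrow(x), " subnetwork(s)",
      if (!is.null(attr(x, "delta"))) sprintf(", delta = %.4g", attr(x, "delta")),
      "\n", sep = "")
  NextMethod()
}
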