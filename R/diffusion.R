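# Insulated heat diffusion over the interactome. The walk matrix W is the
# column-normalized adjacency (W_ij = A_ij / degree(j)); the diffusion
# matrix F = beta * (I - (1 - beta) W)^-1 describes a random walk with
# restart probability beta, so each source retains ("insulates") a share of
# its own heat. F is column-stochastic; the exchanged heat E_ij = F_ij * h_j
# is the heat gene i receives from gene j.

#' Insulated diffusion matrix of a network
#'
#' Computes `F = beta * (I - (1 - beta) W)^-1` by a linear solve per
#' connected component (never by forming the explicit inverse of the full
#' matrix). Isolated nodes are given a self-transition so they retain all
#' their own heat and F stays column-stochastic.
#'
#' @param net an undirected simple `igraph` graph with vertex names.
#' @param beta restart probability in `(0, 1]`; `beta = 1` yields the
#'   identity (no diffusion).
#' @return a dense genes x genes matrix `F` with `beta` as an attribute.
#' @export
insulated_diffusion <- function(net, beta) {
  if (!is.numeric(beta) || beta <= 0 || beta > 1) {
    abort("beta must lie in (0, 1]", class = "netprog_diffusion_error")
  }
  genes <- igraph::V(net)$name
  n <- length(genes)
  F_mat <- matrix(0, n, n, dimnames = list(genes, genes))
  comps <- igraph::components(net, mode = "weak")
  for (k in seq_len(comps$no)) {
    idx <- which(comps$membership == k)
    if (length(idx) == 1) {
      F_mat[idx, idx] <- 1  # isolated node: all heat stays at the source
      next
    }
    sub <- igraph::induced_subgraph(net, idx)
    A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = TRUE))
    W <- sweep(A, 2, colSums(A), "/")
    m <- length(idx)
    F_sub <- beta * solve(diag(m) - (1 - beta) * W)
    F_mat[idx, idx] <- F_sub
  }
  attr(F_mat, "beta") <- beta
  F_mat
}

#' Exchanged-heat matrix
#'
#' `E_ij = F_ij * h_j`: the heat node i receives from source j. Heats absent
#' from the network are ignored with a message; network genes without a heat
#' entry are cold (0).
#'
#' @param F_mat diffusion matrix from [insulated_diffusion()].
#' @param heats named nonnegative numeric vector of gene heat scores, or a
#'   `gene_heat` tibble.
#' @return a genes x genes matrix `E` with column sums equal to the heat
#'   vector.
#' @export
exchanged_heat <- function(F_mat, heats) {
  if (inherits(heats, "gene_heat") || is.data.frame(heats)) {
    heats <- setNames(heats$score, heats$gene)
  }
  if (any(heats < 0)) {
    abort("heat scores must be nonnegative", class = "netprog_diffusion_error")
  }
  genes <- colnames(F_mat)
  extra <- setdiff(names(heats), genes)
  if (length(extra) > 0) {
    inform(sprintf("%d heat-scored gene(s) absent from the network dropped",
                   length(extra)))
  }
  h <- setNames(rep(0, length(genes)), genes)
  common <- intersect(names(heats), genes)
  h[common] <- heats[common]
  E <- sweep(F_mat, 2, h, "*")
  attr(E, "heat") <- h
  E
}

#' Extract hot subnetworks from an exchanged-heat matrix
#'
#' Thresholds `E` at `delta` (arc j -> i iff `E_ij > delta`, i != j), takes
#' strongly connected components of the resulting directed graph, and keeps
#' components with at least `min_size` genes. Induced undirected interactome
#' edges are attached for reporting.
#'
#' @param E exchanged-heat matrix from [exchanged_heat()].
#' @param delta positive threshold on exchanged heat.
#' @param min_size smallest reported component (default 4).
#' @param net the interactome, used for induced edge counts (optional).
#' @return a `subnetwork_set` tibble: `id`, `size`, `genes` (list-column),
#'   `n_edges` (NA without `net`), ordered by decreasing size.
#' @export
extract_subnetworks <- function(E, delta, min_size = 4, net = NULL) {
  if (!is.numeric(delta) || delta <= 0 || !is.finite(delta)) {
    abort("delta must be a positive finite number",
          class = "netprog_diffusion_error")
  }
  genes <- colnames(E)
  adj <- E > delta
  diag(adj) <- FALSE
  # E_ij is heat received by i from j: arc j -> i, i.e. transpose for
  # igraph's row -> column convention.
  g <- igraph::graph_from_adjacency_matrix(t(adj), mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  keep <- which(sizes >= min_size)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  rows <- lapply(seq_along(keep), function(i) {
    members <- sort(genes[comp$membership == keep[i]])
    n_edges <- if (is.null(net)) NA_integer_ else {
      igraph::ecount(igraph::induced_subgraph(
        net, intersect(members, igraph::V(net)$name)))
    }
    tibble(id = paste0("sub_", i), size = length(members),
           genes = list(members), n_edges = n_edges)
  })
  out <- if (length(rows) == 0) {
    tibble(id = character(), size = integer(), genes = list(),
           n_edges = integer())
  } else {
    list_rbind(rows)
  }
  attr(out, "delta") <- delta
  attr(out, "min_size") <- as.integer(min_size)
  structure(out, class = c("subnetwork_set", class(out)))
}

# Largest strongly connected component size of E thresholded at delta.
largest_scc_size <- function(E, delta) {
  adj <- E > delta
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(t(adj), mode = "directed")
  max(igraph::components(g, mode = "strong")$csize)
}

#' Permutation-calibrated exchanged-heat threshold
#'
#' For each exchanged-heat matrix of a heat-permuted ensemble, finds the
#' smallest threshold at which the largest strongly connected component
#' falls below `max_size_cap` nodes, and returns the median over the
#' ensemble. Larger caps give smaller (or equal) thresholds.
#'
#' @param E_list list of >= 10 exchanged-heat matrices computed from
#'   permuted heat vectors.
#' @param max_size_cap component-size cap (default 3: permuted heats may
#'   retain nothing beyond an edge, so no chance component approaches the
#'   reportable size); must be finite and >= 2.
#' @return the median threshold (positive scalar).
#' @export
auto_delta <- function(E_list, max_size_cap = 3) {
  if (length(E_list) < 10) {
    abort("auto_delta needs at least 10 permuted exchanged-heat matrices",
          class = "netprog_diffusion_error")
  }
  if (!is.finite(max_size_cap) || max_size_cap < 2) {
    abort("max_size_cap must be finite and >= 2",
          class = "netprog_diffusion_error")
  }
  per_perm <- vapply(E_list, function(E) {
    vals <- E
    diag(vals) <- 0
    vals <- sort(unique(vals[vals > 0]))
    if (length(vals) == 0) return(NA_real_)
    # monotone in delta: binary search for the smallest value meeting the cap
    lo <- 1L; hi <- length(vals)
    if (largest_scc_size(E, vals[hi]) >= max_size_cap) return(NA_real_)
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (largest_scc_size(E, vals[mid]) < max_size_cap) hi <- mid else lo <- mid + 1L
    }
    vals[lo]
  }, numeric(1))
  if (all(is.na(per_perm))) {
    abort("degenerate ensemble: no positive exchanged heat",
          class = "netprog_diffusion_error")
  }
  median(per_perm, na.rm = TRUE)
}
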