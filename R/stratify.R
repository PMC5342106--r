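# Survival-oriented tumor stratification: pool the stability-selected
# features of every subnetwork model with median C > 0.5, cluster patients
# by consensus non-negative matrix factorization, and compare the strata's
# survival.

#' Pool stability-selected features across retained subnetwork models
#'
#' Takes the union (deduplicated) of stability-selected features over all
#' models with `median_c > 0.5` (strict) and assembles the corresponding
#' patients x features matrix from the core set.
#'
#' @param models a `prognostic_models` tibble (see
#'   [evaluate_subnetworks()]); its `cv_results` attribute supplies the
#'   per-model selection counts.
#' @param ds an `omics_dataset`.
#' @param min_count stability cutoff passed to [stability_select()].
#' @return a list: `matrix` (patients x pooled features, unscaled),
#'   `features`, `modality_counts` tibble.
#' @export
pool_features <- function(models, ds, min_count = 5) {
  keep <- models$median_c > 0.5 & !is.na(models$median_c)
  if (!any(keep)) {
    abort("no model with median C > 0.5", class = "netprog_stratify_error")
  }
  details <- attr(models, "cv_results")
  feats <- unique(unlist(lapply(models$subnetwork[keep], function(id) {
    stability_select(details[[id]]$selection_counts, min_count)
  })))
  if (length(feats) == 0) {
    abort("pooled feature set is empty", class = "netprog_stratify_error")
  }
  feats <- sort(feats)
  cols <- lapply(feats, function(fid) feature_values(ds, fid))
  found <- !vapply(cols, is.null, logical(1))
  x <- do.call(cbind, cols[found])
  colnames(x) <- feats[found]
  rownames(x) <- ds$clinical$patient_id
  tab <- table(sub(":.*$", "", feats[found]))
  list(matrix = x, features = feats[found],
       modality_counts = tibble(modality = names(tab),
                                n = as.integer(tab)))
}

# One NMF factorization V ~ W H by multiplicative (Lee-Seung, Frobenius)
# updates. V is features x patients, nonnegative.
nmf_fit <- function(V, k, n_iter = 200, eps = 1e-9) {
  f <- nrow(V); p <- ncol(V)
  W <- matrix(runif(f * k, 0.1, 1), f, k)
  H <- matrix(runif(k * p, 0.1, 1), k, p)
  for (it in seq_len(n_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
  }
  list(W = W, H = H)
}

#' Consensus NMF clustering of patients
#'
#' Each pooled feature is min-max scaled to `[0, 1]` (a rank-preserving map
#' into the non-negative domain), then `n_runs` NMF factorizations of rank
#' `k` are computed from random initializations; each run labels a patient
#' by their dominant factor. The consensus matrix holds co-clustering
#' frequencies over runs, and the final labels cut the average-linkage
#' hierarchical tree of `1 - consensus` into `k` groups.
#'
#' @param mat patients x features matrix (any scale).
#' @param k number of strata (default 2).
#' @param n_runs NMF restarts (>= 10 for a meaningful consensus).
#' @param seed RNG seed.
#' @param n_iter multiplicative-update iterations per run.
#' @return a `stratification_result`: `labels` tibble (`patient_id`,
#'   `cluster`), `consensus` matrix, `k`, `n_runs`.
#' @export
nmf_consensus <- function(mat, k = 2, n_runs = 50, seed = 1L, n_iter = 200) {
  if (k < 2) abort("k must be >= 2", class = "netprog_stratify_error")
  if (k >= min(dim(mat))) {
    abort("rank k must be below both matrix dimensions",
          class = "netprog_stratify_error")
  }
  rng <- apply(mat, 2, function(col) {
    r <- range(col)
    if (r[1] == r[2]) rep(0.5, length(col)) else (col - r[1]) / (r[2] - r[1])
  })
  V <- t(rng)  # features x patients, in [0, 1]
  n <- ncol(V)
  consensus <- matrix(0, n, n)
  for (run in seq_len(n_runs)) {
    fit <- with_substream(seed, "nmf", rep = run, nmf_fit(V, k, n_iter))
    lab <- apply(fit$H, 2, which.max)
    consensus <- consensus + outer(lab, lab, "==")
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(rownames(mat), rownames(mat))
  final <- cutree(hclust(as.dist(1 - consensus), method = "average"), k = k)
  structure(
    list(labels = tibble(patient_id = rownames(mat),
                         cluster = as.integer(final)),
         consensus = consensus, k = as.integer(k),
         n_runs = as.integer(n_runs)),
    class = "stratification_result"
  )
}

#' Survival comparison between patient strata
#'
#' Kaplan-Meier per cluster, overall log-rank test across clusters, and
#' pairwise Cox hazard ratios with 95% CIs.
#'
#' @param labels tibble (`patient_id`, `cluster`) or a
#'   `stratification_result`.
#' @param surv data frame with `time`, `event` in the same patient order.
#' @return a list: `logrank_p`, `pairwise` tibble (`cluster_a`, `cluster_b`,
#'   `hr`, `ci_low`, `ci_high`, `p`), `km` tibble.
#' @export
compare_strata <- function(labels, surv) {
  if (inherits(labels, "stratification_result")) labels <- labels$labels
  cl <- factor(labels$cluster)
  if (nlevels(cl) < 2) {
    abort("need >= 2 clusters", class = "netprog_stratify_error")
  }
  tab <- table(cl)
  if (any(tab < 2)) {
    abort("every cluster needs >= 2 patients",
          class = "netprog_stratify_error")
  }
  ev <- tapply(surv$event, cl, sum)
  if (any(ev < 1)) {
    abort("every cluster needs >= 1 event", class = "netprog_stratify_error")
  }
  y <- survival::Surv(surv$time, surv$event)
  sd_fit <- survival::survdiff(y ~ cl)
  logrank_p <- pchisq(sd_fit$chisq, df = nlevels(cl) - 1, lower.tail = FALSE)
  pairs <- utils::combn(levels(cl), 2)
  pairwise <- list_rbind(lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sel <- cl %in% c(a, b)
    fit <- survival::coxph(y[sel] ~ I(cl[sel] == a), ties = "efron")
    bb <- coef(fit)[1]; se <- sqrt(fit$var[1, 1])
    tibble(cluster_a = a, cluster_b = b, hr = exp(bb),
           ci_low = exp(bb - qnorm(0.975) * se),
           ci_high = exp(bb + qnorm(0.975) * se),
           p = 2 * stats::pnorm(-abs(bb / se)))
  }))
  km_fit <- survival::survfit(y ~ cl)
  km <- tibble(
    cluster = rep(sub("^cl=", "", names(km_fit$strata)), km_fit$strata),
    time = km_fit$time, n_risk = km_fit$n.risk, n_event = km_fit$n.event,
    survival = km_fit$surv
  )
  list(logrank_p = logrank_p, pairwise = pairwise, km = km)
}

#' @export
print.stratification_result <- function(x, ...) {
  cat("<stratification_result> k = ", x$k, ", ", x$n_runs, " NMF runs\n",
      sep = "")
  print(table(cluster = x$labels$cluster))
  invisible(x)
}

#' Cluster labels of a stratification
#' @param x a `stratification_result`.
#' @param ... unused.
#' @return the labels tibble.
#' @method tidy stratification_result
#' @export
tidy.stratification_result <- function(x, ...) x$labels
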