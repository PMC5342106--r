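# Prognostic evaluation of subnetwork profiles: Monte-Carlo cross-validated
# concordance of elastic-net-penalized Cox models, survival-permutation
# significance, ranking, and the genome-wide molecular baseline.

# Pull per-patient values for one feature id ("modality:row") from a
# dataset. Methylation ids address probe rows.
feature_values <- function(ds, feature_id) {
  parts <- strsplit(feature_id, ":", fixed = TRUE)[[1]]
  mat <- switch(parts[1], mrna = ds$mrna, cnv = ds$cnv,
                methylation = ds$methylation,
                abort(paste0("unknown modality in feature id: ", feature_id)))
  key <- paste(parts[-1], collapse = ":")
  if (!key %in% rownames(mat)) return(NULL)
  as.numeric(mat[key, ])
}

#' Assemble the multi-omic profile of a subnetwork
#'
#' Builds the patients x features matrix of the screened-in (selected)
#' features of the member genes — mRNA, CNV, and the collapsed methylation
#' probe — with z-standardized columns. The profile depends only on the gene
#' set, not on which interactome produced it.
#'
#' @param genes character vector of member genes, or a one-row
#'   `subnetwork_set` slice.
#' @param ds an `omics_dataset`.
#' @param screened a collapsed `screening_result`.
#' @return a numeric matrix, patients in rows (core-set order), feature ids
#'   in columns.
#' @export
assemble_profile <- function(genes, ds, screened) {
  if (is.data.frame(genes)) genes <- unlist(genes$genes)
  feats <- screened[screened$selected & screened$gene %in% genes, ,
                    drop = FALSE]
  if (nrow(feats) == 0) {
    abort(paste0("no selected features for subnetwork genes: ",
                 paste(head(genes, 5), collapse = ", ")),
          class = "netprog_profile_error")
  }
  cols <- lapply(feats$feature_id, function(fid) feature_values(ds, fid))
  found <- !vapply(cols, is.null, logical(1))
  if (any(!found)) {
    inform(sprintf("%d feature(s) absent from the dataset matrices dropped",
                   sum(!found)))
  }
  x <- do.call(cbind, cols[found])
  colnames(x) <- feats$feature_id[found]
  rownames(x) <- ds$clinical$patient_id
  scale(x)[, , drop = FALSE]
}

# One penalized-Cox train/test evaluation. Returns test C and the selected
# feature names. The elastic net is a feature-*selection* step: when the
# inner CV favors the empty null end of the path, the fit steps down to the
# largest penalty admitting at least one feature, so every split contributes
# a feature set (as the stability-selection counts assume) and a
# non-degenerate test statistic. A split where even that fails scores 0.5.
fit_split <- function(x, time, event, train, cfg) {
  x_tr <- x[train, , drop = FALSE]
  x_te <- x[-train, , drop = FALSE]
  y_tr <- survival::Surv(time[train], event[train])
  fit_enet <- function() {
    if (ncol(x) >= 2) {
      foldid <- sample(rep(seq_len(cfg$lambda_nfolds),
                           length.out = nrow(x_tr)))
      cvfit <- glmnet::cv.glmnet(x_tr, y_tr, family = "cox",
                                 alpha = cfg$enet_mix,
                                 nlambda = cfg$nlambda, foldid = foldid,
                                 standardize = FALSE)
      beta <- as.numeric(coef(cvfit, s = "lambda.min"))
      if (all(beta == 0)) {
        nz <- which(cvfit$glmnet.fit$df > 0)
        if (length(nz) > 0) {
          beta <- as.numeric(coef(cvfit$glmnet.fit,
                                  s = cvfit$glmnet.fit$lambda[nz[1]]))
        }
      }
      beta
    } else {
      fit <- survival::coxph(y_tr ~ x_tr[, 1], ties = "efron")
      as.numeric(coef(fit))
    }
  }
  beta <- tryCatch(
    suppressWarnings(fit_enet()),
    error = function(e) rep(0, ncol(x)))
  if (anyNA(beta)) beta[is.na(beta)] <- 0
  if (all(beta == 0)) {
    return(list(c_index = 0.5, selected = character(0)))
  }
  lp <- as.numeric(x_te %*% beta)
  c_idx <- tryCatch(concordance_index(lp, time[-train], event[-train]),
                    error = function(e) 0.5)
  list(c_index = c_idx, selected = colnames(x)[beta != 0])
}

#' Monte-Carlo cross-validated concordance of a feature profile
#'
#' Repeats `cfg$n_cv_splits` random `train_frac`/`1 - train_frac` splits.
#' Per split an elastic-net-penalized Cox model (mixing `cfg$enet_mix`,
#' penalty strength by inner `cfg$lambda_nfolds`-fold partial-likelihood CV)
#' is trained; the linear predictor is scored on the held-out patients by
#' Harrell's C. Splits whose training or test part has no event are redrawn.
#' The median test C over splits is the profile's predictive value, and
#' per-feature selection counts accumulate across splits for stability
#' selection.
#'
#' @param profile patients x features matrix (see [assemble_profile()]).
#' @param surv data frame with `time` and `event` in profile row order.
#' @param cfg an [analysis_config()].
#' @param n_splits optionally override `cfg$n_cv_splits`.
#' @param seed_label substream label (internal; keeps permutation re-runs
#'   independent of the observed run).
#' @param seed optionally override `cfg$seed`.
#' @return a `cv_result`: list with `splits` tibble (`split`, `c_index`,
#'   `n_selected`), `median_c`, `c_distribution`, `selection_counts` tibble.
#' @export
monte_carlo_cv <- function(profile, surv, cfg = analysis_config(),
                           n_splits = cfg$n_cv_splits,
                           seed_label = "cv", seed = cfg$seed) {
  n <- nrow(profile)
  if (n < 20) abort("need >= 20 patients", class = "netprog_cv_error")
  if (sum(surv$event) < 10) {
    abort("need >= 10 events", class = "netprog_cv_error")
  }
  n_train <- round(cfg$train_frac * n)
  counts <- setNames(rep(0L, ncol(profile)), colnames(profile))
  redraws <- 0L
  res <- lapply(seq_len(n_splits), function(s) {
    with_substream(seed, seed_label, rep = s, {
      for (try in 1:100) {
        train <- sample.int(n, n_train)
        if (sum(surv$event[train]) >= 1 && sum(surv$event[-train]) >= 1) break
        redraws <<- redraws + 1L
      }
      fit_split(profile, surv$time, surv$event, train, cfg)
    })
  })
  if (redraws > 0) inform(sprintf("%d event-free split(s) redrawn", redraws))
  for (r in res) counts[r$selected] <- counts[r$selected] + 1L
  cs <- vapply(res, `[[`, numeric(1), "c_index")
  structure(
    list(
      splits = tibble(split = seq_len(n_splits), c_index = cs,
                      n_selected = vapply(res, function(r) length(r$selected),
                                          integer(1))),
      median_c = median(cs),
      c_distribution = cs,
      selection_counts = tibble(feature = names(counts),
                                count = as.integer(counts))
    ),
    class = "cv_result"
  )
}

#' Survival-permutation significance of a profile's median concordance
#'
#' Jointly permutes the `(time, event)` pairs across patients
#' `cfg$n_permutations` times, re-runs the Monte-Carlo CV on each permuted
#' outcome (with the reduced `cfg$n_perm_splits` budget), and reports the
#' add-one empirical p-value of the observed median C:
#' `p = (#{permuted median >= observed} + 1) / (n_permutations + 1)`.
#'
#' @param profile patients x features matrix.
#' @param surv data frame with `time`, `event`.
#' @param observed_median_c median C of the unpermuted data.
#' @param cfg an [analysis_config()].
#' @return a list: `p_value`, `permuted_medians`.
#' @export
permutation_test <- function(profile, surv, observed_median_c,
                             cfg = analysis_config()) {
  if (cfg$n_permutations < 20) {
    abort("n_permutations must be >= 20", class = "netprog_cv_error")
  }
  n <- nrow(profile)
  perm_medians <- vapply(seq_len(cfg$n_permutations), function(p) {
    idx <- with_substream(cfg$seed, "perm-shuffle", rep = p, sample.int(n))
    surv_p <- surv[idx, , drop = FALSE]
    monte_carlo_cv(profile, surv_p, cfg, n_splits = cfg$n_perm_splits,
                   seed_label = paste0("perm-cv-", p))$median_c
  }, numeric(1))
  list(
    p_value = (sum(perm_medians >= observed_median_c) + 1) /
      (cfg$n_permutations + 1),
    permuted_medians = perm_medians
  )
}

#' Evaluate and rank discovered subnetworks
#'
#' For each subnetwork: assembles the profile, runs [monte_carlo_cv()] and
#' [permutation_test()], and flags models passing the filter
#' `median C > 0.5` and `permutation p < 0.05`. Models are ranked by median
#' C descending, ties broken by permutation p ascending then id.
#'
#' @param subnetworks a `subnetwork_set`.
#' @param ds an `omics_dataset`.
#' @param screened a collapsed `screening_result`.
#' @param cfg an [analysis_config()].
#' @return a `prognostic_models` object: tibble (`subnetwork`, `size`,
#'   `median_c`, `permutation_p`, `passed`, `rank`) with per-model
#'   `cv_results` stored as an attribute.
#' @export
evaluate_subnetworks <- function(subnetworks, ds, screened,
                                 cfg = analysis_config()) {
  surv <- ds$clinical[, c("time", "event")]
  details <- list()
  rows <- lapply(seq_len(nrow(subnetworks)), function(i) {
    id <- subnetworks$id[i]
    profile <- tryCatch(
      assemble_profile(subnetworks$genes[[i]], ds, screened),
      error = function(e) NULL)
    if (is.null(profile)) {
      return(tibble(subnetwork = id, size = subnetworks$size[i],
                    median_c = NA_real_, permutation_p = NA_real_,
                    passed = FALSE))
    }
    cv <- monte_carlo_cv(profile, surv, cfg, seed_label = paste0("cv-", id))
    pt <- permutation_test(profile, surv, cv$median_c, cfg)
    details[[id]] <<- c(cv, list(permutation = pt))
    tibble(subnetwork = id, size = subnetworks$size[i],
           median_c = cv$median_c, permutation_p = pt$p_value,
           passed = cv$median_c > 0.5 & pt$p_value < 0.05)
  })
  out <- rank_models(list_rbind(rows))
  attr(out, "cv_results") <- details
  structure(out, class = c("prognostic_models", class(out)))
}

#' Rank prognostic models by predictive power
#'
#' @param models tibble with `subnetwork`, `median_c`, `permutation_p`.
#' @return the tibble ordered by median C (descending), permutation p
#'   (ascending), then id, with a `rank` column.
#' @export
rank_models <- function(models) {
  out <- models |>
    arrange(desc(.data$median_c), .data$permutation_p, .data$subnetwork)
  out$rank <- seq_len(nrow(out))
  out
}

#' Genome-wide molecular baseline model
#'
#' The non-network comparator: inside every training split, all features of
#' the requested modalities are pre-selected by univariate Cox
#' (likelihood-ratio `p < alpha_screen`), then an elastic-net Cox model is
#' fitted on the survivors and scored on the held-out patients, exactly as
#' in [monte_carlo_cv()]. Pre-selection inside the split avoids information
#' leaking from test to train.
#'
#' @param ds an `omics_dataset`.
#' @param modalities subset of `c("mrna", "cnv", "methylation")`.
#' @param cfg an [analysis_config()].
#' @param screened optional collapsed `screening_result` used only to
#'   restrict methylation to the collapsed probes.
#' @return a `cv_result`.
#' @export
baseline_molecular_model <- function(ds, modalities, cfg = analysis_config(),
                                     screened = NULL) {
  if (length(modalities) == 0) {
    abort("modality set must not be empty", class = "netprog_cv_error")
  }
  modalities <- match.arg(modalities, c("mrna", "cnv", "methylation"),
                          several.ok = TRUE)
  blocks <- list()
  if ("mrna" %in% modalities) {
    blocks$mrna <- t(ds$mrna); colnames(blocks$mrna) <-
      paste0("mrna:", rownames(ds$mrna))
  }
  if ("cnv" %in% modalities) {
    blocks$cnv <- t(ds$cnv); colnames(blocks$cnv) <-
      paste0("cnv:", rownames(ds$cnv))
  }
  if ("methylation" %in% modalities) {
    meth <- ds$methylation
    if (!is.null(screened)) {
      keep <- screened$probe[screened$modality == "methylation"]
      meth <- meth[rownames(meth) %in% keep, , drop = FALSE]
    }
    blocks$methylation <- t(meth)
    colnames(blocks$methylation) <- paste0("methylation:", rownames(meth))
  }
  x <- scale(do.call(cbind, blocks))
  x <- x[, !vapply(seq_len(ncol(x)), function(j) anyNA(x[, j]), logical(1)),
         drop = FALSE]
  surv <- ds$clinical[, c("time", "event")]
  n <- nrow(x)
  n_train <- round(cfg$train_frac * n)
  cs <- vapply(seq_len(cfg$n_cv_splits), function(s) {
    with_substream(cfg$seed, "baseline", rep = s, {
      for (try in 1:100) {
        train <- sample.int(n, n_train)
        if (sum(surv$event[train]) >= 2 && sum(surv$event[-train]) >= 1) break
      }
      # univariate Cox pre-selection on the training part only
      keep <- vapply(seq_len(ncol(x)), function(j) {
        xt <- x[train, j]
        if (sd(xt) == 0) return(FALSE)
        f <- tryCatch(
          survival::coxph.fit(matrix(xt, ncol = 1),
                              survival::Surv(surv$time[train],
                                             surv$event[train]),
                              strata = NULL, offset = NULL, init = NULL,
                              control = survival::coxph.control(),
                              weights = NULL, method = "efron",
                              rownames = NULL),
          error = function(e) NULL)
        if (is.null(f) || anyNA(f$coefficients)) return(FALSE)
        p <- pchisq(max(0, 2 * (f$loglik[2] - f$loglik[1])), 1,
                    lower.tail = FALSE)
        p < cfg$alpha_screen
      }, logical(1))
      if (!any(keep)) return(0.5)
      fit_split(x[, keep, drop = FALSE], surv$time, surv$event, train,
                cfg)$c_index
    })
  }, numeric(1))
  structure(
    list(splits = tibble(split = seq_len(cfg$n_cv_splits), c_index = cs,
                         n_selected = NA_integer_),
         median_c = median(cs), c_distribution = cs,
         selection_counts = tibble(feature = character(), count = integer())),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", length(x$c_distribution), " splits, median C = ",
      format(x$median_c, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Per-split C-indexes of a cross-validation result
#' @param x a `cv_result`.
#' @param ... unused.
#' @return tibble with one row per split.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$splits

#' One-row summary of a cross-validation result
#' @param x a `cv_result`.
#' @param ... unused.
#' @return tibble: `n_splits`, `median_c`, `iqr_low`, `iqr_high`.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  q <- quantile(x$c_distribution, c(0.25, 0.75), names = FALSE)
  tibble(n_splits = length(x$c_distribution), median_c = x$median_c,
         iqr_low = q[1], iqr_high = q[2])
}
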