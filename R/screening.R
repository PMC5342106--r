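# Per-feature age-adjusted Cox screening. Each (gene, modality) feature is
# fitted in a two-covariate proportional-hazards model (feature + age) with
# Efron tie handling; significance is the 1-df likelihood-ratio test of the
# full model against the age-only model. No multiple-testing correction is
# applied at this stage: the raw p < alpha rule defines the survival-related
# feature set feeding the heat score.

# Low-level Cox fit via survival::coxph.fit (verified identical to coxph();
# avoids per-call formula overhead across thousands of features).
cox_lrt_fit <- function(x_full, x_null, time, event) {
  y <- survival::Surv(time, event)
  ctrl <- survival::coxph.control()
  fit <- tryCatch(
    survival::coxph.fit(x_full, y, strata = NULL, offset = NULL, init = NULL,
                        control = ctrl, weights = NULL, method = "efron",
                        rownames = NULL),
    error = function(e) NULL)
  null <- tryCatch(
    survival::coxph.fit(x_null, y, strata = NULL, offset = NULL, init = NULL,
                        control = ctrl, weights = NULL, method = "efron",
                        rownames = NULL),
    error = function(e) NULL)
  list(fit = fit, null = null)
}

#' Fit an age-adjusted Cox model for one molecular feature
#'
#' Fits the partial likelihood of `(feature, age)` on overall survival and
#' tests the feature by the 1-df likelihood-ratio test against the age-only
#' model. Hazard direction is coded `"P"` (HR > 1, worse prognosis) or `"G"`
#' (HR < 1, better prognosis). The feature is used as supplied (not
#' rescaled); [screen_features()] standardizes before calling.
#'
#' @param feature numeric per-patient vector.
#' @param age per-patient age in years.
#' @param time,event overall survival time (> 0) and event indicator (0/1).
#' @return a one-row tibble: `coef` (log HR per unit), `hr`, `ci_low`,
#'   `ci_high` (95% CI of HR), `p_lrt`, `n_used`, `direction`, `status`
#'   (`"ok"`, `"degenerate"`, or `"nonconvergent"`).
#' @export
fit_feature_cox <- function(feature, age, time, event) {
  keep <- complete.cases(feature, age, time, event)
  feature <- feature[keep]; age <- age[keep]
  time <- time[keep]; event <- event[keep]
  n_used <- length(feature)
  na_row <- function(status) {
    tibble(coef = NA_real_, hr = NA_real_, ci_low = NA_real_,
           ci_high = NA_real_, p_lrt = NA_real_, n_used = n_used,
           direction = NA_character_, status = status)
  }
  if (n_used < 3 || sum(event) < 2) return(na_row("degenerate"))
  if (sd(feature) == 0) return(na_row("degenerate"))
  fits <- cox_lrt_fit(cbind(feature = feature, age = age),
                      matrix(age, ncol = 1), time, event)
  if (is.null(fits$fit) || is.null(fits$null) ||
      anyNA(fits$fit$coefficients) ||
      any(abs(fits$fit$coefficients) > 15) ||
      any(diag(fits$fit$var) <= 0)) {
    return(na_row("nonconvergent"))
  }
  b <- fits$fit$coefficients[["feature"]]
  se <- sqrt(fits$fit$var[1, 1])
  lrt <- max(0, 2 * (fits$fit$loglik[2] - fits$null$loglik[2]))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  tibble(
    coef = b, hr = exp(b),
    ci_low = exp(b - qnorm(0.975) * se),
    ci_high = exp(b + qnorm(0.975) * se),
    p_lrt = p, n_used = n_used,
    direction = if (exp(b) > 1) "P" else "G",
    status = "ok"
  )
}

#' Screen every (gene, modality) feature against overall survival
#'
#' Runs [fit_feature_cox()] for every row of the mRNA, CNV, and methylation
#' matrices (features are z-standardized first so coefficients are
#' comparable across modalities), and marks as selected the features with
#' `p_lrt < alpha_screen`. Degenerate or non-convergent features are never
#' selected.
#'
#' @param ds an `omics_dataset` (core set already built).
#' @param cfg an [analysis_config()].
#' @return a `screening_result`: a tibble with columns `feature_id`, `gene`,
#'   `probe` (NA outside methylation), `modality`, the [fit_feature_cox()]
#'   statistics, and `selected`.
#' @export
screen_features <- function(ds, cfg = analysis_config()) {
  stopifnot(inherits(ds, "omics_dataset"))
  clin <- ds$clinical
  screen_block <- function(mat, modality, gene_of) {
    if (is.null(mat) || nrow(mat) == 0) return(NULL)
    rows <- lapply(seq_len(nrow(mat)), function(i) {
      x <- as.numeric(mat[i, ])
      s <- sd(x, na.rm = TRUE)
      if (is.finite(s) && s > 0) x <- (x - mean(x, na.rm = TRUE)) / s
      fit_feature_cox(x, clin$age, clin$time, clin$event)
    })
    out <- list_rbind(rows)
    out$feature_id <- paste0(modality, ":", rownames(mat))
    out$gene <- gene_of
    out$probe <- if (modality == "methylation") rownames(mat) else NA_character_
    out$modality <- modality
    out
  }
  meth_genes <- ds$probe_map$gene[match(rownames(ds$methylation),
                                        ds$probe_map$probe)]
  stats <- bind_rows(
    screen_block(ds$mrna, "mrna", rownames(ds$mrna)),
    screen_block(ds$cnv, "cnv", rownames(ds$cnv)),
    screen_block(ds$methylation, "methylation", meth_genes)
  )
  stats <- stats[, c("feature_id", "gene", "probe", "modality", "coef", "hr",
                     "ci_low", "ci_high", "p_lrt", "n_used", "direction",
                     "status")]
  stats$selected <- stats$status == "ok" & stats$p_lrt < cfg$alpha_screen
  if (!any(stats$selected)) {
    warn("no feature passed the screening cutoff")
  }
  structure(as_tibble(stats), class = c("screening_result", class(stats)))
}

#' Collapse methylation probes to one per gene
#'
#' Among the probes mapping to a gene, keeps the probe most associated with
#' survival — operationalized as the smallest age-adjusted likelihood-ratio
#' p-value, with ties broken by the lexicographically smallest probe id.
#' Probes that failed to fit are only retained when no probe of the gene
#' fitted. Other modalities pass through unchanged.
#'
#' @param screened a `screening_result`.
#' @return a `screening_result` with at most one methylation row per gene.
#' @export
collapse_methylation <- function(screened) {
  meth <- screened[screened$modality == "methylation", , drop = FALSE]
  if (nrow(meth) == 0) return(screened)
  keep <- meth |>
    mutate(.p = ifelse(.data$status == "ok", .data$p_lrt, Inf)) |>
    arrange(.data$gene, .data$.p, .data$probe) |>
    group_by(.data$gene) |>
    slice(1) |>
    ungroup() |>
    pull(.data$feature_id)
  out <- screened[screened$modality != "methylation" |
                    screened$feature_id %in% keep, , drop = FALSE]
  structure(out, class = class(screened))
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> ", nrow(x), " features, ",
      sum(x$selected), " selected\n", sep = "")
  counts <- table(x$modality[x$selected])
  if (length(counts) > 0) {
    cat("  selected by modality: ",
        paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

#' Summarize a screening result
#' @param x a `screening_result`.
#' @param ... unused.
#' @return one row per modality: features fitted, selected, selection rate.
#' @method glance screening_result
#' @export
glance.screening_result <- function(x, ...) {
  x |>
    group_by(.data$modality) |>
    summarise(n_features = n(), n_selected = sum(.data$selected),
              frac_selected = mean(.data$selected), .groups = "drop")
}
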