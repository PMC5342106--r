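# Subnetwork risk scores (snRS): stability selection over the CV splits,
# an unpenalized multivariable Cox fit for the weights, a linear risk score
# per patient, median-split stratification with Kaplan-Meier / log-rank
# evaluation, and the clinically adjusted Cox table.

#' Stability-selected feature set
#'
#' Keeps the features selected strictly more than `min_count` times across
#' the Monte-Carlo CV splits; consistent selection rules out random
#' selection bias for any single split.
#'
#' @param counts tibble with `feature`, `count` (from a `cv_result`), or a
#'   named numeric vector.
#' @param min_count strict lower bound (default 5: "more than 5 times").
#' @return character vector of feature ids.
#' @export
stability_select <- function(counts, min_count = 5) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$count, counts$feature)
  }
  out <- names(counts)[counts > min_count]
  if (length(out) == 0) {
    warn("no feature passed stability selection")
  }
  sort(out)
}

#' Fit the final multivariable Cox model of a subnetwork
#'
#' Unpenalized Cox regression of survival on the stability-selected features
#' over the full cohort; the coefficients become the snRS weights. On
#' non-convergence or collinearity the fit falls back to a barely penalized
#' ridge Cox (reported in the result).
#'
#' @param features character vector of feature ids (profile column names).
#' @param profile patients x features matrix containing those columns.
#' @param surv data frame with `time`, `event` in profile row order.
#' @return a `risk_model`: `features`, `coefficients` (named), `se`,
#'   `fallback` flag, `n`, `n_events`.
#' @export
fit_final_model <- function(features, profile, surv) {
  if (length(features) < 1) {
    abort("no features to fit", class = "netprog_risk_error")
  }
  missing_f <- setdiff(features, colnames(profile))
  if (length(missing_f) > 0) {
    abort(paste0("features absent from profile: ",
                 paste(missing_f, collapse = ", ")),
          class = "netprog_risk_error")
  }
  if (sum(surv$event) < length(features) + 2) {
    abort("too few events for an unpenalized multivariable fit",
          class = "netprog_risk_error")
  }
  x <- profile[, features, drop = FALSE]
  y <- survival::Surv(surv$time, surv$event)
  fit <- NULL
  ok <- qr(cbind(x))$rank == ncol(x)
  if (ok) {
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(y ~ x, ties = "efron"),
        warning = function(w) {
          ok <<- FALSE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(coef(fit)) || any(abs(coef(fit)) > 15)) {
      ok <- FALSE
    }
  }
  fallback <- !ok
  if (fallback) {
    inform("multivariable Cox unstable (collinearity or non-convergence): ridge fallback")
    # near-unpenalized ridge; glmnet needs >= 2 columns
    xx <- if (ncol(x) == 1) cbind(x, jitter_zero = 0) else x
    rf <- glmnet::glmnet(xx, y, family = "cox", alpha = 0,
                         lambda = 1e-4, standardize = FALSE)
    beta <- as.numeric(coef(rf))[seq_len(ncol(x))]
    se <- rep(NA_real_, ncol(x))
  } else {
    beta <- as.numeric(coef(fit))
    se <- sqrt(diag(fit$var))
  }
  structure(
    list(features = features,
         coefficients = setNames(beta, features),
         se = setNames(se, features),
         fallback = fallback,
         n = nrow(x), n_events = sum(surv$event)),
    class = "risk_model"
  )
}

#' Subnetwork risk score (snRS) per patient
#'
#' Linear combination of the model's feature values with the trained Cox
#' coefficients: `snRS_i = sum_f coef_f * x_{f,i}`. In `mrna_only` mode —
#' the external-validation mode, where only expression is measured — the
#' mRNA features and their *training* coefficients are used, with no refit
#' or renormalization.
#'
#' @param model a `risk_model`.
#' @param profile patients x features matrix with patient rownames.
#' @param mrna_only apply only the `mrna:` features of the model.
#' @return tibble: `patient_id`, `snrs`.
#' @export
snrs <- function(model, profile, mrna_only = FALSE) {
  feats <- model$features
  if (mrna_only) {
    feats <- feats[startsWith(feats, "mrna:")]
    if (length(feats) == 0) {
      abort("model has no mRNA features", class = "netprog_risk_error")
    }
  }
  missing_f <- setdiff(feats, colnames(profile))
  if (length(missing_f) > 0) {
    abort(paste0("profile lacks model features: ",
                 paste(missing_f, collapse = ", ")),
          class = "netprog_risk_error")
  }
  score <- as.numeric(profile[, feats, drop = FALSE] %*%
                        model$coefficients[feats])
  tibble(patient_id = rownames(profile), snrs = score)
}

#' Median-split risk stratification with survival comparison
#'
#' Splits the cohort at the median snRS (`> median` = high risk, ties go to
#' low risk), and compares the groups by Kaplan-Meier curves, the log-rank
#' test, and a Cox hazard ratio of high vs low with 95% CI.
#'
#' @param scores tibble from [snrs()] (`patient_id`, `snrs`).
#' @param surv data frame with `time`, `event` in the same patient order.
#' @return a `risk_stratification`: `assignments` tibble (`patient_id`,
#'   `snrs`, `group`), `cutoff`, `logrank_p`, `hr`, `ci_low`, `ci_high`,
#'   `km` tibble (`group`, `time`, `n_risk`, `n_event`, `survival`,
#'   `std_err`).
#' @export
stratify_median <- function(scores, surv) {
  s <- scores$snrs
  if (sd(s) == 0) {
    abort("degenerate risk score: all values identical",
          class = "netprog_risk_error")
  }
  cutoff <- median(s)
  group <- factor(ifelse(s > cutoff, "high", "low"),
                  levels = c("low", "high"))
  if (min(table(group)) < 2) {
    abort("fewer than 2 patients in a risk group",
          class = "netprog_risk_error")
  }
  y <- survival::Surv(surv$time, surv$event)
  sd_fit <- survival::survdiff(y ~ group)
  logrank_p <- pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(y ~ group, ties = "efron")
  b <- coef(cx)[1]; se <- sqrt(cx$var[1, 1])
  km_fit <- survival::survfit(y ~ group, conf.type = "log")
  km <- tibble(
    group = rep(sub("^group=", "", names(km_fit$strata)),
                km_fit$strata),
    time = km_fit$time, n_risk = km_fit$n.risk, n_event = km_fit$n.event,
    survival = km_fit$surv, std_err = km_fit$std.err * km_fit$surv
  )
  structure(
    list(assignments = tibble(patient_id = scores$patient_id, snrs = s,
                              group = as.character(group)),
         cutoff = cutoff, logrank_p = logrank_p,
         hr = exp(b), ci_low = exp(b - qnorm(0.975) * se),
         ci_high = exp(b + qnorm(0.975) * se),
         km = km),
    class = "risk_stratification"
  )
}

#' Univariate and multivariable clinically adjusted Cox table
#'
#' Reports, for the snRS and each clinical covariate (age, stage dichotomized
#' III/IV vs I/II, lymph node count, tumor weight), the univariate hazard
#' ratio, then one multivariable model with the snRS and all usable
#' covariates. The snRS enters as a continuous variable. Constant covariates
#' are dropped with a message.
#'
#' @param scores tibble from [snrs()].
#' @param clinical clinical tibble including `time`, `event`, and the
#'   covariate columns present.
#' @return tibble: `variable`, `analysis` (`"univariate"`/`"multivariable"`),
#'   `hr`, `ci_low`, `ci_high`, `p`.
#' @export
clinical_adjustment <- function(scores, clinical) {
  df <- left_join(scores, clinical, by = "patient_id")
  covs <- list(snrs = df$snrs)
  if ("age" %in% names(df)) covs$age <- df$age
  if ("stage" %in% names(df)) {
    covs$stage_high <- as.numeric(df$stage %in% c("III", "IV"))
  }
  if ("lymph_node_count" %in% names(df)) {
    covs$lymph_node_count <- df$lymph_node_count
  }
  if ("tumor_weight" %in% names(df)) covs$tumor_weight <- df$tumor_weight
  keep <- vapply(covs, function(v) sd(v, na.rm = TRUE) > 0, logical(1))
  if (any(!keep)) {
    inform(paste0("constant covariate(s) dropped: ",
                  paste(names(covs)[!keep], collapse = ", ")))
  }
  covs <- covs[keep]
  y <- survival::Surv(df$time, df$event)
  row_of <- function(fit, term, analysis) {
    i <- match(term, names(coef(fit)))
    b <- coef(fit)[i]; se <- sqrt(diag(fit$var))[i]
    tibble(variable = term, analysis = analysis, hr = exp(b),
           ci_low = exp(b - qnorm(0.975) * se),
           ci_high = exp(b + qnorm(0.975) * se),
           p = 2 * stats::pnorm(-abs(b / se)))
  }
  uni <- list_rbind(lapply(names(covs), function(v) {
    fit <- survival::coxph(y ~ covs[[v]], ties = "efron")
    names(fit$coefficients) <- v
    row_of(fit, v, "univariate")
  }))
  xm <- do.call(cbind, covs)
  rank_ok <- qr(xm)$rank == ncol(xm)
  if (!rank_ok) {
    inform("collinear covariates in multivariable model: ridge fallback")
    rf <- glmnet::glmnet(xm, y, family = "cox", alpha = 0, lambda = 1e-4,
                         standardize = FALSE)
    beta <- as.numeric(coef(rf))
    multi <- tibble(variable = colnames(xm), analysis = "multivariable",
                    hr = exp(beta), ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_)
  } else {
    fit <- survival::coxph(y ~ xm, ties = "efron")
    names(fit$coefficients) <- colnames(xm)
    multi <- list_rbind(lapply(colnames(xm), function(v) {
      row_of(fit, v, "multivariable")
    }))
  }
  bind_rows(uni, multi)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> ", length(x$features), " feature(s), n = ", x$n,
      " (", x$n_events, " events)",
      if (x$fallback) " [ridge fallback]", "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Coefficients of a risk model
#' @param x a `risk_model`.
#' @param ... unused.
#' @return tibble: `feature`, `estimate`, `std_error`.
#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  tibble(feature = x$features, estimate = unname(x$coefficients),
         std_error = unname(x$se))
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat("<risk_stratification> cutoff = ", format(x$cutoff, digits = 4),
      ", log-rank p = ", format(x$logrank_p, digits = 4),
      ", HR = ", format(x$hr, digits = 4),
      " [", format(x$ci_low, digits = 4), ", ",
      format(x$ci_high, digits = 4), "]\n", sep = "")
  invisible(x)
}

#' One-row summary of a risk stratification
#' @param x a `risk_stratification`.
#' @param ... unused.
#' @return tibble: group sizes, cutoff, log-rank p, HR and CI.
#' @method glance risk_stratification
#' @export
glance.risk_stratification <- function(x, ...) {
  tab <- table(x$assignments$group)
  tibble(n_high = as.integer(tab[["high"]]), n_low = as.integer(tab[["low"]]),
         cutoff = x$cutoff, logrank_p = x$logrank_p, hr = x$hr,
         ci_low = x$ci_low, ci_high = x$ci_high)
}
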