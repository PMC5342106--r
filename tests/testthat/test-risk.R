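test_that("stability selection is strictly greater-than", {
  counts <- c(a = 6, b = 5, c = 100)
  expect_setequal(stability_select(counts, 5), c("a", "c"))
  expect_length(suppressWarnings(stability_select(c(a = 0, b = 0), 5)), 0)
  expect_warning(stability_select(c(a = 0), 5))
  expect_setequal(stability_select(counts, 0), c("a", "b", "c"))
  # tibble interface as produced by monte_carlo_cv
  tb <- tibble::tibble(feature = c("x", "y"), count = c(10L, 2L))
  expect_identical(stability_select(tb, 5), "x")
})

test_that("the final Cox fit matches coxph and recovers planted effects", {
  set.seed(34)
  n <- 300
  x <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("f1", "f2")))
  sv <- sim_surv(0.6 * x[, 1] - 0.4 * x[, 2], cens_frac = 0.2)
  m <- fit_final_model(c("f1", "f2"), x, sv)
  ref <- survival::coxph(survival::Surv(sv$time, sv$event) ~ x,
                         ties = "efron")
  expect_equal(unname(m$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_false(m$fallback)

  # single feature reduces to the univariate fit
  m1 <- fit_final_model("f1", x, sv)
  ref1 <- survival::coxph(survival::Surv(sv$time, sv$event) ~ x[, 1])
  expect_equal(unname(m1$coefficients), unname(coef(ref1)),
               tolerance = 1e-10)

  # duplicated columns trigger the ridge fallback
  xd <- cbind(x, f3 = x[, 1])
  expect_message(md <- fit_final_model(c("f1", "f2", "f3"), xd, sv),
                 "fallback")
  expect_true(md$fallback)
  expect_true(all(is.finite(md$coefficients)))

  expect_error(fit_final_model(c("f1", "nope"), x, sv),
               class = "netprog_risk_error")
  expect_error(fit_final_model(character(0), x, sv),
               class = "netprog_risk_error")
})

test_that("snRS is the stated linear combination and rank-invariant to shifts", {
  x <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4,
              dimnames = list(paste0("p", 1:4), c("mrna:g1", "cnv:g1")))
  model <- structure(list(features = colnames(x),
                          coefficients = c("mrna:g1" = 1, "cnv:g1" = 0),
                          se = c(NA, NA), fallback = FALSE, n = 4,
                          n_events = 4),
                     class = "risk_model")
  s <- snrs(model, x)
  expect_equal(s$snrs, x[, "mrna:g1"], ignore_attr = TRUE)

  # affine shift of a feature shifts scores but not the median split
  x2 <- x; x2[, 1] <- x2[, 1] + 100
  s2 <- snrs(model, x2)
  expect_equal(s2$snrs - s$snrs, rep(100, 4))
  expect_identical(s$snrs > median(s$snrs), s2$snrs > median(s2$snrs))

  # mRNA-only mode uses the training coefficients untouched
  before <- model$coefficients
  sm <- snrs(model, x[, 1, drop = FALSE], mrna_only = TRUE)
  expect_identical(model$coefficients, before)
  expect_equal(sm$snrs, x[, 1], ignore_attr = TRUE)

  expect_error(snrs(model, x[, 2, drop = FALSE]),
               class = "netprog_risk_error")
})

test_that("median split balances groups and refuses degenerate scores", {
  set.seed(35)
  n <- 41
  scores <- tibble::tibble(patient_id = paste0("p", 1:n), snrs = rnorm(n))
  sv <- sim_surv(rep(0, n), cens_frac = 0.2)
  strat <- stratify_median(scores, sv)
  tab <- table(strat$assignments$group)
  expect_lte(abs(tab[["high"]] - tab[["low"]]), 1)
  # the patient at the median goes to the low-risk group
  at_cut <- strat$assignments$group[scores$snrs == strat$cutoff]
  expect_true(all(at_cut == "low"))

  expect_error(
    stratify_median(tibble::tibble(patient_id = "a", snrs = 1)[c(1, 1), ],
                    sv[1:2, ]),
    class = "netprog_risk_error")
})

test_that("strong risk separation is detected by the log-rank test", {
  set.seed(36)
  n <- 60
  risk <- rnorm(n)
  sv <- sim_surv(1.5 * risk, cens_frac = 0.1)
  strat <- stratify_median(tibble::tibble(patient_id = paste0("p", 1:n),
                                          snrs = risk), sv)
  expect_lt(strat$logrank_p, 0.05)
  expect_gt(strat$hr, 1)
  expect_true(all(c("time", "n_risk", "n_event", "survival") %in%
                    names(strat$km)))
})

test_that("log-rank agrees with the observed-minus-expected oracle", {
  # 6 patients, alternating groups, one censored
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- rep(c("low", "high"), 3)
  sd_fit <- survival::survdiff(
    survival::Surv(time, event) ~ group)
  expect_equal(unname(sd_fit$chisq), brute_logrank(time, event, group),
               tolerance = 1e-10)

  set.seed(37)
  for (r in 1:20) {
    n <- sample(6:10, 1)
    tt <- sample(1:8, n, replace = TRUE)
    ee <- rbinom(n, 1, 0.8)
    gg <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(gg)) < 2 || sum(ee) == 0) next
    chi <- tryCatch(brute_logrank(tt, ee, gg), error = function(e) NA)
    if (is.na(chi) || !is.finite(chi)) next
    ref <- unname(survival::survdiff(survival::Surv(tt, ee) ~ gg)$chisq)
    expect_equal(chi, ref, tolerance = 1e-8)
  }
})

test_that("clinical adjustment reports stable HRs and drops constants", {
  set.seed(38)
  n <- 400
  snrs_val <- rnorm(n)
  sv <- sim_surv(0.8 * snrs_val, cens_frac = 0.25)
  clinical <- tibble::tibble(
    patient_id = sprintf("p%03d", 1:n),
    age = rnorm(n, 55, 10),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
    lymph_node_count = rpois(n, 3),
    tumor_weight = rlnorm(n, log(30), 0.4),
    time = sv$time, event = sv$event)
  scores <- tibble::tibble(patient_id = clinical$patient_id, snrs = snrs_val)
  adj <- clinical_adjustment(scores, clinical)
  hr_uni <- adj$hr[adj$variable == "snrs" & adj$analysis == "univariate"]
  hr_multi <- adj$hr[adj$variable == "snrs" & adj$analysis == "multivariable"]
  # snRS independent of the clinical covariates: adjustment barely moves it
  expect_gt(hr_multi / hr_uni, 0.8)
  expect_lt(hr_multi / hr_uni, 1.25)

  # all-early-stage cohort: the stage term is dropped
  clin2 <- clinical
  clin2$stage <- "I"
  adj2 <- quietly(clinical_adjustment(scores, clin2))
  expect_false("stage_high" %in% adj2$variable)

  # a duplicate of the snRS forces the collinearity fallback
  clin3 <- clinical
  clin3$tumor_weight <- snrs_val
  expect_message(clinical_adjustment(scores, clin3), "fallback|collinear")
})
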