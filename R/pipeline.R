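# End-to-end pipeline: screen -> heat -> discover -> evaluate -> risk ->
# stratify, with every table written as TSV (config-hash header comment) and
# summaries as JSON. Given one config + seed the outputs are byte-identical
# across runs.

# Small FNV-style hash of the configuration, written into output headers so
# every table is traceable to the exact parameter set that produced it.
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 999999937
  sprintf("%09d", h)
}

write_tsv_hashed <- function(df, path, cfg) {
  writeLines(paste0("# config_hash: ", config_hash(cfg)), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Run the full discovery-to-stratification pipeline
#'
#' Executes every stage on an aligned dataset and interactome and writes the
#' stage outputs under `out_dir`: `screening.tsv`, `gene_heat.tsv`,
#' `subnetworks.tsv` + `subnetworks.gmt`, `cv_cindex.tsv`, `models.tsv`,
#' `selection_counts.tsv`, `snrs.tsv`, `km.tsv`, `risk_summary.json`,
#' `clinical_adjustment.tsv`, `clusters.tsv`, `consensus.tsv`,
#' `strata_survival.json`, and a `run_summary.json`. Stages whose inputs are
#' degenerate on a given dataset (no subnetwork, no passed model, no pooled
#' feature) are skipped and recorded in the summary. Outputs are
#' byte-identical across runs with the same config and seed.
#'
#' @param ds an `omics_dataset` (core set built).
#' @param net the interactome (`igraph`).
#' @param cfg an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(ds, net, cfg = analysis_config(), out_dir = NULL) {
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    if (persist) write_tsv_hashed(df, file.path(out_dir, name), cfg)
  }
  emit_json <- function(x, name) {
    if (persist) {
      jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                           digits = 10, pretty = TRUE)
    }
  }
  summary <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                  n_patients = nrow(ds$clinical),
                  n_events = sum(ds$clinical$event))

  screened <- collapse_methylation(screen_features(ds, cfg))
  emit(screened, "screening.tsv")
  summary$n_selected_features <- sum(screened$selected)

  heat <- gene_heat(screened)
  emit(heat, "gene_heat.tsv")
  summary$n_survival_genes <- length(survival_gene_set(heat))

  subs <- discover_subnetworks(net, heat, cfg)
  subs_flat <- subs |>
    mutate(genes = vapply(.data$genes, paste, character(1), collapse = ";"),
           delta = attr(subs, "delta"), beta = attr(subs, "beta"))
  emit(subs_flat, "subnetworks.tsv")
  if (persist && nrow(subs) > 0) {
    write_gmt(setNames(subs$genes, subs$id),
              file.path(out_dir, "subnetworks.gmt"),
              description = paste0("size_class_p=", subs$size_class_p))
  }
  summary$n_subnetworks <- nrow(subs)
  summary$delta <- attr(subs, "delta")

  models <- NULL; risk <- NULL; strata <- NULL
  if (nrow(subs) > 0) {
    models <- evaluate_subnetworks(subs, ds, screened, cfg)
    details <- attr(models, "cv_results")
    cv_long <- list_rbind(lapply(names(details), function(id) {
      d <- details[[id]]$splits
      tibble(subnetwork = id, split = d$split, c_index = d$c_index)
    }))
    emit(cv_long, "cv_cindex.tsv")
    emit(as_tibble(models), "models.tsv")
    counts_long <- list_rbind(lapply(names(details), function(id) {
      d <- details[[id]]$selection_counts
      tibble(subnetwork = id, feature = d$feature, count = d$count)
    }))
    emit(counts_long, "selection_counts.tsv")
    summary$n_passed_models <- sum(models$passed)

    top <- models$subnetwork[models$passed][1]
    if (!is.na(top) && length(top) == 1) {
      feats <- stability_select(details[[top]]$selection_counts,
                                cfg$stability_min_count)
      if (length(feats) > 0) {
        profile <- assemble_profile(
          subs$genes[[match(top, subs$id)]], ds, screened)
        final <- fit_final_model(feats, profile,
                                 ds$clinical[, c("time", "event")])
        scores <- snrs(final, profile)
        strat <- stratify_median(scores, ds$clinical[, c("time", "event")])
        emit(strat$assignments, "snrs.tsv")
        emit(strat$km, "km.tsv")
        adj <- clinical_adjustment(scores, ds$clinical)
        emit(adj, "clinical_adjustment.tsv")
        emit_json(list(subnetwork = top, features = final$features,
                       coefficients = as.list(final$coefficients),
                       cutoff = strat$cutoff, logrank_p = strat$logrank_p,
                       hr = strat$hr, ci_low = strat$ci_low,
                       ci_high = strat$ci_high),
                  "risk_summary.json")
        risk <- list(model = final, stratification = strat, adjusted = adj)
        summary$risk_subnetwork <- top
      } else {
        summary$risk_subnetwork <- NA
      }
    }

    pooled <- tryCatch(pool_features(models, ds, cfg$stability_min_count),
                       error = function(e) NULL)
    if (!is.null(pooled)) {
      nmf <- nmf_consensus(pooled$matrix, k = cfg$nmf_k,
                           n_runs = cfg$nmf_runs, seed = cfg$seed)
      cmp <- tryCatch(
        compare_strata(nmf, ds$clinical[, c("time", "event")]),
        error = function(e) NULL)
      emit(nmf$labels, "clusters.tsv")
      cons <- as_tibble(as.data.frame(nmf$consensus))
      cons <- bind_cols(tibble(patient_id = rownames(nmf$consensus)), cons)
      emit(cons, "consensus.tsv")
      if (!is.null(cmp)) {
        emit_json(list(logrank_p = cmp$logrank_p,
                       pairwise = cmp$pairwise), "strata_survival.json")
      }
      strata <- list(pooled = pooled[c("features", "modality_counts")],
                     result = nmf, comparison = cmp)
      summary$n_pooled_features <- length(pooled$features)
      summary$n_clusters <- cfg$nmf_k
    }
  }
  emit_json(summary, "run_summary.json")
  invisible(list(screened = screened, heat = heat, subnetworks = subs,
                 models = models, risk = risk, strata = strata,
                 summary = summary))
}
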