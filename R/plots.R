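# ggplot2 views of the pipeline's result objects.

#' @importFrom ggplot2 ggplot aes geom_histogram geom_boxplot geom_step
#'   geom_tile geom_hline labs facet_wrap scale_fill_viridis_c autoplot
NULL

#' @export
ggplot2::autoplot

#' Screening p-value histograms per modality
#' @param object a `screening_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot screening_result
#' @export
autoplot.screening_result <- function(object, ...) {
  df <- object[object$status == "ok", , drop = FALSE]
  ggplot(df, aes(x = .data$p_lrt)) +
    geom_histogram(breaks = seq(0, 1, 0.05), fill = "grey35") +
    facet_wrap(~modality) +
    labs(x = "age-adjusted LRT p-value", y = "features",
         title = "Per-feature survival screening")
}

#' Heat-score distribution over survival-related genes
#' @param object a `gene_heat` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gene_heat
#' @export
autoplot.gene_heat <- function(object, ...) {
  df <- object[object$score > 0, , drop = FALSE]
  ggplot(df, aes(x = .data$score)) +
    geom_histogram(bins = 30, fill = "firebrick") +
    labs(x = "gene heat score (-2 sum log p)", y = "genes",
         title = "Survival-related gene heat")
}

#' Cross-validated C-index distribution
#' @param object a `cv_result`.
#' @param ... unused.
#' @return a ggplot (boxplot of the split C-indexes, chance level marked).
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot(object$splits, aes(x = "", y = .data$c_index)) +
    geom_boxplot(width = 0.3, fill = "steelblue") +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    labs(x = NULL, y = "test C-index",
         title = sprintf("Monte-Carlo CV (median C = %.3f)",
                         object$median_c))
}

#' Kaplan-Meier curves of a median-split risk stratification
#' @param object a `risk_stratification`.
#' @param ... unused.
#' @return a ggplot with one survival step curve per risk group.
#' @method autoplot risk_stratification
#' @export
autoplot.risk_stratification <- function(object, ...) {
  km0 <- object$km |>
    group_by(.data$group) |>
    summarise(time = 0, survival = 1, .groups = "drop")
  km <- bind_rows(km0, object$km[, c("group", "time", "survival")])
  ggplot(km, aes(x = .data$time, y = .data$survival,
                 colour = .data$group)) +
    geom_step() +
    labs(x = "time", y = "survival probability",
         title = sprintf("snRS median split (log-rank p = %.3g)",
                         object$logrank_p))
}

#' Consensus co-clustering matrix of an NMF stratification
#' @param object a `stratification_result`.
#' @param ... unused.
#' @return a ggplot tile map, patients ordered by cluster.
#' @method autoplot stratification_result
#' @export
autoplot.stratification_result <- function(object, ...) {
  ord <- order(object$labels$cluster)
  m <- object$consensus[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- m[cbind(df$i, df$j)]
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = "co-clustering\nfrequency",
                         limits = c(0, 1)) +
    labs(x = NULL, y = NULL, title = "Consensus NMF")
}
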