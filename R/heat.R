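# Fisher-combined gene heat scores. For each gene the screened-in modality
# p-values are combined as score = -2 * sum(log p) — Fisher's method for
# independent tests — so a gene touched on several omic levels accumulates
# heat. Genes with no screened-in feature score 0 and stay cold.

#' Combine screened modality p-values into per-gene heat scores
#'
#' Computes `score = -2 * sum(log(p_m))` over the *selected* features of each
#' gene, at most one p-value per modality (methylation must already be
#' collapsed to one probe per gene; see [collapse_methylation()]). Exact
#' zeros are floored at the smallest positive double. Genes present in the
#' screening result but with no selected feature get score 0.
#'
#' @param screened a `screening_result` after probe collapse.
#' @return a `gene_heat` tibble: `gene`, `score`, `p_mrna`, `p_cnv`,
#'   `p_methylation` (NA where the modality was not selected).
#' @export
#' @examples
#' # a gene selected at p = 0.05 in two modalities scores
#' -2 * (log(0.05) + log(0.05))
gene_heat <- function(screened) {
  meth <- screened[screened$modality == "methylation", , drop = FALSE]
  if (any(duplicated(meth$gene))) {
    abort("multiple methylation probes per gene: run collapse_methylation() first",
          class = "netprog_heat_error")
  }
  sel <- screened[screened$selected, , drop = FALSE]
  if (nrow(sel) > 0 && any(sel$p_lrt == 0)) {
    inform("p-value of 0 floored at .Machine$double.xmin")
    sel$p_lrt[sel$p_lrt == 0] <- .Machine$double.xmin
  }
  wide <- sel |>
    select("gene", "modality", "p_lrt") |>
    tidyr::pivot_wider(names_from = "modality", values_from = "p_lrt",
                       names_prefix = "p_")
  for (col in c("p_mrna", "p_cnv", "p_methylation")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  all_genes <- sort(unique(screened$gene))
  out <- tibble(gene = all_genes) |>
    left_join(wide, by = "gene")
  pmat <- as.matrix(out[, c("p_mrna", "p_cnv", "p_methylation")])
  out$score <- -2 * rowSums(log(pmat), na.rm = TRUE)
  out <- out[, c("gene", "score", "p_mrna", "p_cnv", "p_methylation")]
  structure(out, class = c("gene_heat", class(out)))
}

#' Survival-related gene set
#'
#' Genes with a strictly positive heat score, i.e. at least one screened-in
#' modality feature.
#'
#' @param heats a `gene_heat` tibble from [gene_heat()].
#' @return a character vector of gene symbols.
#' @export
survival_gene_set <- function(heats) {
  sort(heats$gene[heats$score > 0])
}

#' @export
print.gene_heat <- function(x, ...) {
  cat("<gene_heat> ", nrow(x), " genes, ", sum(x$score > 0),
      " survival-related (score > 0)\n", sep = "")
  NextMethod()
}
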