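# Readers and writers for the on-disk formats: TSV feature matrices keyed by
# gene symbol (probe id for methylation), a two-column edge list, a clinical
# table, and GMT gene sets. Patient alignment across modalities is by id
# intersection (the "core set"). Symbol matching is case-sensitive exact.

#' Read a feature matrix from TSV
#'
#' First column is the feature id (gene symbol, or probe id for methylation);
#' remaining columns are patients. Cells must be numeric or NA.
#'
#' @param path TSV file.
#' @param modality one of `"mrna"`, `"cnv"`, `"methylation"`.
#' @return a numeric matrix (features x patients) with a `modality` attribute.
#' @export
read_feature_matrix <- function(path, modality = c("mrna", "cnv", "methylation")) {
  modality <- match.arg(modality)
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), comment = "#", progress = FALSE)
  if (ncol(df) < 2) abort("feature matrix needs an id column plus >= 1 patient")
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate feature ids: ", paste(unique(dup), collapse = ", ")),
          class = "netprog_io_error")
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = list(ids, colnames(cells))))
  bad <- which(is.na(num) & !is.na(cells) & cells != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric cell at row '%s', column '%s'",
                  ids[bad[1, 1]], colnames(cells)[bad[1, 2]]),
          class = "netprog_io_error")
  }
  attr(num, "modality") <- modality
  num
}

#' Write a feature matrix to TSV
#' @param mat features x patients numeric matrix with dimnames.
#' @param path output file.
#' @param id_col header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(mat, path, id_col = "feature") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a PPI network from a two-column edge list
#'
#' Duplicate and reversed edges are merged, self-loops dropped (with a
#' message giving the count), and isolated endpoints kept.
#'
#' @param path TSV with two gene-symbol columns (no header required; a
#'   header line is detected when both fields repeat nowhere as an edge).
#' @return an undirected simple `igraph` graph with vertex names.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = c("a", "b"))
  if (nrow(df) == 0) abort("empty edge list", class = "netprog_io_error")
  loops <- df$a == df$b
  if (any(loops)) {
    inform(sprintf("dropped %d self-loop(s)", sum(loops)))
  }
  nodes <- unique(c(df$a, df$b))
  df <- df[!loops, , drop = FALSE]
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a two-column edge list
#' @param net an `igraph` graph.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the clinical/survival table
#'
#' Requires columns `patient_id`, `time`, `event`; any further columns (age,
#' stage, lymph_node_count, tumor_weight, ...) are carried along.
#'
#' @param path TSV file.
#' @return a tibble, one row per patient.
#' @export
read_clinical <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), comment = "#",
                        progress = FALSE)
  need <- c("patient_id", "time", "event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("clinical table lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "netprog_io_error")
  }
  if (any(df$time <= 0)) {
    abort("survival times must be positive", class = "netprog_io_error")
  }
  if (!all(df$event %in% c(0, 1))) {
    abort("event indicator must be 0 or 1", class = "netprog_io_error")
  }
  df$event <- as.integer(df$event)
  as_tibble(df)
}

#' Align modalities and clinical data on the core patient set
#'
#' The core set is the intersection of patient ids across all provided
#' feature matrices and the clinical table; matrices are reordered to the
#' clinical core-set order and dropped patients are reported. Features with
#' more than `max_missing` missing values in the core set are removed; the
#' remainder are median-imputed.
#'
#' @param mrna,cnv,methylation feature matrices (see [read_feature_matrix()]).
#' @param clinical clinical tibble (see [read_clinical()]).
#' @param probe_map tibble with columns `probe`, `gene` for methylation.
#' @param max_missing maximum tolerated fraction of missing values per
#'   feature (default 0.2).
#' @return an `omics_dataset` restricted to the core set.
#' @export
build_core_set <- function(mrna, cnv, methylation, clinical, probe_map,
                           max_missing = 0.2) {
  ids <- Reduce(intersect, list(colnames(mrna), colnames(cnv),
                                colnames(methylation), clinical$patient_id))
  if (length(ids) == 0) abort("empty core set", class = "netprog_io_error")
  dropped <- length(unique(c(colnames(mrna), colnames(cnv),
                             colnames(methylation), clinical$patient_id))) -
    length(ids)
  if (dropped > 0) {
    inform(sprintf("core set: %d patients; %d id(s) absent from >= 1 modality dropped",
                   length(ids), dropped))
  }
  clinical <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
  clean <- function(m) {
    m <- m[, ids, drop = FALSE]
    frac_na <- rowMeans(is.na(m))
    if (any(frac_na > max_missing)) {
      inform(sprintf("dropped %d feature(s) with > %.0f%% missing",
                     sum(frac_na > max_missing), 100 * max_missing))
      m <- m[frac_na <= max_missing, , drop = FALSE]
    }
    if (anyNA(m)) {
      med <- apply(m, 1, median, na.rm = TRUE)
      idx <- which(is.na(m), arr.ind = TRUE)
      m[idx] <- med[idx[, 1]]
    }
    m
  }
  methylation <- clean(methylation)
  probe_map <- probe_map[probe_map$probe %in% rownames(methylation), ,
                         drop = FALSE]
  structure(
    list(mrna = clean(mrna), cnv = clean(cnv), methylation = methylation,
         probe_map = as_tibble(probe_map), clinical = clinical),
    class = "omics_dataset"
  )
}

#' Write an `omics_dataset` as a directory of TSV files
#'
#' Emits `mrna.tsv`, `cnv.tsv`, `methylation.tsv`, `probe_map.tsv`,
#' `clinical.tsv` in the formats the readers accept, so simulated cohorts
#' feed the pipeline through the same path as external data.
#'
#' @param ds an `omics_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_omics_dir <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(ds$mrna, file.path(dir, "mrna.tsv"), "gene")
  write_feature_matrix(ds$cnv, file.path(dir, "cnv.tsv"), "gene")
  write_feature_matrix(ds$methylation, file.path(dir, "methylation.tsv"),
                       "probe")
  readr::write_tsv(ds$probe_map, file.path(dir, "probe_map.tsv"),
                   progress = FALSE)
  readr::write_tsv(ds$clinical, file.path(dir, "clinical.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read an `omics_dataset` from a directory written by [write_omics_dir()]
#' @param dir directory containing the five TSV files.
#' @return an `omics_dataset` aligned on the core set.
#' @export
read_omics_dir <- function(dir) {
  build_core_set(
    mrna = read_feature_matrix(file.path(dir, "mrna.tsv"), "mrna"),
    cnv = read_feature_matrix(file.path(dir, "cnv.tsv"), "cnv"),
    methylation = read_feature_matrix(file.path(dir, "methylation.tsv"),
                                      "methylation"),
    clinical = read_clinical(file.path(dir, "clinical.tsv")),
    probe_map = readr::read_tsv(file.path(dir, "probe_map.tsv"),
                                col_types = "cc", progress = FALSE)
  )
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors (gene sets).
#' @param path output file.
#' @param description per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "netprog") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
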