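#' Read a tab-delimited expression matrix with sample metadata
#'
#' Expression files follow the GEO series-matrix layout: a header row of
#' sample ids, a first column of probe ids, and log2 intensities in the
#' body. Metadata is a CSV keyed by `sample_id`; every sample column in the
#' expression file must appear there.
#'
#' @param path Tab-delimited expression file (probes x samples, log2 scale).
#' @param meta_path CSV of per-sample metadata with a `sample_id` column,
#'   or `NULL` to skip the metadata join.
#' @return A list with `expr` (tibble: `probe_id` + one numeric column per
#'   sample) and `meta` (tibble of sample metadata, `NULL` when no
#'   `meta_path` was given).
#' @export
read_expression <- function(path, meta_path = NULL) {
  lines <- readr::read_lines(path)
  if (length(lines) < 1) abort("empty expression file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(fields)
  if (any(width != width[1])) {
    bad <- which(width != width[1])[1]
    abort(sprintf("ragged row at line %d: %d fields, expected %d",
                  bad, width[bad], width[1]))
  }
  sample_ids <- fields[[1]][-1]
  body <- fields[-1]
  probe_ids <- vapply(body, `[[`, "", 1)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(sample_ids)))
  )
  if (length(sample_ids) == 1) vals <- matrix(vals, nrow = 1)
  bad_cells <- which(colSums(is.na(vals)) > 0)
  if (length(bad_cells)) {
    abort(sprintf("non-numeric value at line %d", bad_cells[1] + 1L))
  }
  m <- t(vals)
  if (length(sample_ids) == 1) m <- matrix(vals, ncol = 1)
  rownames(m) <- probe_ids
  colnames(m) <- sample_ids
  expr <- matrix_to_expr(m)
  validate_expr(expr)

  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- readr::read_csv(meta_path, show_col_types = FALSE)
    if (!"sample_id" %in% names(meta)) abort("metadata must have a sample_id column")
    orphan <- setdiff(sample_ids, meta$sample_id)
    if (length(orphan)) {
      abort(paste0("samples absent from metadata: ", paste(orphan, collapse = ", ")))
    }
    meta <- meta[match(sample_ids, meta$sample_id), ]
  }
  list(expr = expr, meta = meta)
}

#' Write an expression tibble to the tab-delimited matrix format
#'
#' Values are written at full precision (17 significant digits) so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param expr Expression tibble (`probe_id` + sample columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expr(expr)
  m <- expr_to_matrix(expr)
  header <- paste(c("probe_id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 17, scientific = FALSE,
                                   trim = TRUE)),
          collapse = "\t")
  }, "")
  readr::write_lines(c(header, rows), path)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common distribution given by the
#' across-sample mean of order statistics. Ties within a column receive the
#' mean of the corresponding reference values. Probe and sample order are
#' preserved, and the operation is idempotent.
#'
#' @param expr Expression tibble with at least two sample columns.
#' @return Quantile-normalized expression tibble of the same shape.
#' @export
quantile_normalize <- function(expr) {
  validate_expr(expr, min_samples = 2)
  m <- expr_to_matrix(expr)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  matrix_to_expr(out)
}

#' Load a probe annotation table
#'
#' @param path Delimited file (TSV or CSV) with columns `probe_id`,
#'   `symbol`, `ensembl_id`, `biotype`; `biotype` must be `"gene"` or
#'   `"lncRNA"`.
#' @return Annotation tibble.
#' @export
load_annotation <- function(path) {
  ann <- readr::read_delim(path, show_col_types = FALSE)
  needed <- c("probe_id", "symbol", "ensembl_id", "biotype")
  if (!all(needed %in% names(ann))) {
    abort(paste0("annotation must have columns: ", paste(needed, collapse = ", ")))
  }
  validate_annotation(ann[needed])
}

validate_annotation <- function(ann) {
  if (nrow(ann) == 0) return(as_tibble(ann))
  if (anyDuplicated(ann$probe_id)) {
    abort(paste0("duplicate probe_id in annotation: ",
                 ann$probe_id[duplicated(ann$probe_id)][1]))
  }
  bad <- setdiff(unique(ann$biotype), c("gene", "lncRNA"))
  if (length(bad)) abort(paste0("unknown biotype: ", paste(bad, collapse = ", ")))
  as_tibble(ann)
}

#' Partition an annotation into gene and lncRNA probe sets
#'
#' @param ann Annotation tibble (see [load_annotation()]).
#' @return List with character vectors `gene` and `lncRNA`; the two are
#'   disjoint and together cover every annotated probe.
#' @export
split_biotypes <- function(ann) {
  ann <- validate_annotation(ann)
  list(
    gene   = ann$probe_id[ann$biotype == "gene"],
    lncRNA = ann$probe_id[ann$biotype == "lncRNA"]
  )
}

#' Read a gene-lncRNA pair table
#'
#' Reads the pair-report format used throughout the package: one row per
#' co-expressed pair with columns `lnc_probe`, `lnc_symbol`, `gene_probe`,
#' `gene_symbol`, `r` (Pearson correlation), `time`.
#'
#' @param path TSV file; defaults columns as above.
#' @return Tibble of pairs sorted by descending correlation.
#' @export
read_pair_table <- function(path) {
  pairs <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("lnc_probe", "lnc_symbol", "gene_probe", "gene_symbol", "r", "time")
  if (!all(needed %in% names(pairs))) {
    abort(paste0("pair table must have columns: ", paste(needed, collapse = ", ")))
  }
  dplyr::arrange(as_tibble(pairs[needed]), dplyr::desc(.data$r))
}

#' Derive a probe annotation from a pair table
#'
#' Useful for the bundled pair fixture, where biotype is implied by which
#' side of the pair a probe occurs on.
#'
#' @param pairs Pair tibble (see [read_pair_table()]).
#' @return Annotation tibble with `ensembl_id = NA`.
#' @export
annotation_from_pairs <- function(pairs) {
  lnc <- dplyr::distinct(pairs, probe_id = .data$lnc_probe, symbol = .data$lnc_symbol) |>
    dplyr::mutate(biotype = "lncRNA")
  gene <- dplyr::distinct(pairs, probe_id = .data$gene_probe, symbol = .data$gene_symbol) |>
    dplyr::mutate(biotype = "gene")
  validate_annotation(
    dplyr::bind_rows(lnc, gene) |>
      dplyr::distinct(.data$probe_id, .keep_all = TRUE) |>
      dplyr::mutate(ensembl_id = NA_character_, .before = "biotype")
  )
}

#' Path to a bundled example table
#'
#' @param file File name under the package's `extdata/` (e.g.
#'   `"table1_pairs.tsv"`, `"table2_predictors.tsv"`); `NULL` lists them.
#' @return Full path, or a character vector of available files.
#' @export
radsens_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "radsens")))
  }
  path <- system.file("extdata", file, package = "radsens")
  if (path == "") abort(paste0("no bundled file called ", file))
  path
}
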