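#' Construct an expression study
#'
#' Bundles a gene-by-sample matrix of log2 intensities with its per-sample
#' metadata. This is the raw input of the corpus-building stage: every
#' (compound, time point) cell is later contrasted treated versus matched
#' control.
#'
#' @param values Numeric matrix of log2 intensities, genes in rows, samples
#'   in columns. Column names must match `sample_meta$sample_id`; row names
#'   (if present) must match `gene_ids`.
#' @param sample_meta Data frame with columns `sample_id`, `compound_id`,
#'   `time_point` (numeric ordinal, e.g. days), `dose_group` (`"control"` or
#'   `"treated"`) and `replicate`.
#' @param gene_ids Character vector of unique gene identifiers, one per row
#'   of `values`. Defaults to `rownames(values)`.
#' @return An object of class `expression_study` with elements `values`,
#'   `sample_meta`, `gene_ids`, `time_points` (the sorted unique time
#'   ordinals) and `compounds`.
#' @export
expression_study <- function(values, sample_meta, gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) .stopf("expression values must be numeric")
  if (anyNA(values)) .stopf("expression matrix contains missing values; impute or drop before loading")
  if (is.null(gene_ids)) .stopf("gene_ids are required (rownames or explicit)")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values))
    .stopf("gene_ids length (%d) != number of rows (%d)", length(gene_ids), nrow(values))
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) .stopf("duplicate gene_ids: %s", paste(utils::head(dup, 5), collapse = ", "))

  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "compound_id", "time_point", "dose_group", "replicate")
  miss <- setdiff(need, names(sample_meta))
  if (length(miss)) .stopf("sample_meta lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(sample_meta) != ncol(values))
    .stopf("sample_meta rows (%d) != number of samples (%d)", nrow(sample_meta), ncol(values))
  if (!is.null(colnames(values)) &&
      !identical(as.character(sample_meta$sample_id), colnames(values)))
    .stopf("sample_meta$sample_id does not match the column order of `values`")
  bad <- setdiff(unique(sample_meta$dose_group), c("control", "treated"))
  if (length(bad)) .stopf("dose_group must be 'control' or 'treated' (got: %s)",
                          paste(bad, collapse = ", "))
  sample_meta$time_point <- as.numeric(sample_meta$time_point)
  if (anyNA(sample_meta$time_point)) .stopf("time_point must be numeric ordinals")

  rownames(values) <- gene_ids
  structure(
    list(values = values,
         sample_meta = sample_meta,
         gene_ids = gene_ids,
         time_points = sort(unique(sample_meta$time_point)),
         compounds = unique(as.character(sample_meta$compound_id))),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  %d compounds, time points: %s\n",
              length(x$compounds), paste(x$time_points, collapse = ", ")))
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' The expression file has `gene_id` as its first column and one column per
#' sample; the sample sheet has columns `sample_id`, `compound_id`,
#' `time_point`, `dose_group`, `replicate`. Sample-sheet rows are matched to
#' expression columns by `sample_id`.
#'
#' @param expr_path Path to the gene-by-sample TSV matrix.
#' @param samples_path Path to the sample-sheet TSV.
#' @return An [expression_study()].
#' @export
read_expression <- function(expr_path, samples_path) {
  if (!file.exists(expr_path)) .stopf("expression file not found: %s", expr_path)
  if (!file.exists(samples_path)) .stopf("sample sheet not found: %s", samples_path)
  tab <- utils::read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) .stopf("expression file needs a gene_id column plus >=1 sample column")
  gene_ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  meta <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  miss <- setdiff(as.character(meta$sample_id), colnames(values))
  if (length(miss)) .stopf("sample sheet names samples absent from the matrix: %s",
                           paste(utils::head(miss, 5), collapse = ", "))
  values <- values[, as.character(meta$sample_id), drop = FALSE]
  expression_study(values, meta, gene_ids)
}

#' Write an expression study to TSV files
#'
#' Inverse of [read_expression()].
#'
#' @param study An [expression_study()].
#' @param expr_path,samples_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(study, expr_path, samples_path) {
  tab <- data.frame(gene_id = study$gene_ids, study$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$sample_meta, samples_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, samples_path))
}
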