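#' Treated-versus-control fold changes for one compound-time condition
#'
#' Contrasts the treated replicates against the matched controls at a single
#' time point. Replicates are averaged in log2 space; the reported fold
#' change is linear and direction-normalized, i.e.
#' `2^|mean(log2 treated) - mean(log2 control)|`, always >= 1, with the
#' direction recording the sign of the difference (ties count as "up").
#'
#' @param study An [expression_study()].
#' @param compound Compound identifier.
#' @param time Time-point ordinal (must exist in the study).
#' @return Data frame with one row per gene: `gene_id`, `compound_id`,
#'   `time_point`, `fold_change`, `direction`, `log2_fc` (signed).
#' @export
compute_fold_changes <- function(study, compound, time) {
  stopifnot(inherits(study, "expression_study"))
  meta <- study$sample_meta
  sel <- meta$compound_id == compound & meta$time_point == time
  trt <- sel & meta$dose_group == "treated"
  ctl <- sel & meta$dose_group == "control"
  if (!any(trt) || !any(ctl))
    .stopf("contrast unavailable for compound '%s' at time %s: missing %s samples",
           compound, format(time),
           paste(c("treated", "control")[!c(any(trt), any(ctl))], collapse = " and "))
  diff <- rowMeans(study$values[, trt, drop = FALSE]) -
    rowMeans(study$values[, ctl, drop = FALSE])
  data.frame(
    gene_id = study$gene_ids,
    compound_id = compound,
    time_point = time,
    fold_change = 2^abs(diff),
    direction = ifelse(diff >= 0, "up", "down"),
    log2_fc = diff,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag differentially expressed genes
#'
#' Marks records whose absolute log2 fold change reaches `threshold`. The
#' record order is preserved; nothing is dropped, so the caller can inspect
#' the full contrast.
#'
#' @param records Fold-change records from [compute_fold_changes()] (rows
#'   from several conditions may be concatenated).
#' @param threshold Non-negative log2 fold-change cutoff; the default 1
#'   corresponds to a two-fold change.
#' @return `records` with a logical `is_deg` column.
#' @export
select_degs <- function(records, threshold = 1) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) || threshold < 0)
    .stopf("threshold must be a single non-negative number")
  records$is_deg <- log2(records$fold_change) >= threshold
  records
}

#' Build a direction-split vocabulary
#'
#' Every gene contributes two words, `<gene>_up` and `<gene>_down`, so that
#' induction and repression of the same gene are distinct tokens. Word ids
#' are 0-based line numbers: gene `i` (0-based) owns ids `2i` (up) and
#' `2i + 1` (down).
#'
#' @param gene_ids Character vector of unique gene identifiers.
#' @return An object of class `dtm_vocabulary`: `words` (character, length
#'   `2 * length(gene_ids)`), `gene_ids`, and `index` (named lookup from word
#'   to 0-based id).
#' @export
build_vocabulary <- function(gene_ids) {
  gene_ids <- as.character(gene_ids)
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) .stopf("duplicate gene_ids: %s", paste(unique(dup), collapse = ", "))
  if (!length(gene_ids)) .stopf("empty gene universe")
  words <- as.vector(rbind(paste0(gene_ids, "_up"), paste0(gene_ids, "_down")))
  index <- stats::setNames(seq_along(words) - 1L, words)
  structure(list(words = words, gene_ids = gene_ids, index = index),
            class = "dtm_vocabulary")
}

#' @export
print.dtm_vocabulary <- function(x, ...) {
  cat(sprintf("dtm_vocabulary: %d words over %d genes\n",
              length(x$words), length(x$gene_ids)))
  invisible(x)
}

#' Decode words back to (gene, direction)
#'
#' @param vocabulary A [build_vocabulary()] object.
#' @param word_ids Integer vector of 0-based word ids.
#' @return Data frame with `word_id`, `word`, `gene_id`, `direction`.
#' @export
decode_words <- function(vocabulary, word_ids) {
  word_ids <- as.integer(word_ids)
  if (any(word_ids < 0L | word_ids >= length(vocabulary$words)))
    .stopf("word id out of range")
  data.frame(
    word_id = word_ids,
    word = vocabulary$words[word_ids + 1L],
    gene_id = vocabulary$gene_ids[word_ids %/% 2L + 1L],
    direction = c("up", "down")[word_ids %% 2L + 1L],
    stringsAsFactors = FALSE)
}

# Internal constructor shared by encode_documents() and the corpus reader.
.new_corpus <- function(vocabulary, documents, slice_labels) {
  slice_index <- vapply(documents, `[[`, integer(1), "slice_index")
  n_slices <- length(slice_labels)
  slice_sizes <- tabulate(slice_index + 1L, nbins = n_slices)
  doc_meta <- data.frame(
    doc_id = vapply(documents, `[[`, character(1), "doc_id"),
    compound_id = vapply(documents, `[[`, character(1), "compound_id"),
    time_point = vapply(documents, `[[`, numeric(1), "time_point"),
    slice_index = slice_index,
    stringsAsFactors = FALSE)
  structure(list(vocabulary = vocabulary, documents = documents,
                 slice_sizes = slice_sizes, slice_labels = slice_labels,
                 doc_meta = doc_meta),
            class = "dtm_corpus")
}

#' @export
print.dtm_corpus <- function(x, ...) {
  cat(sprintf("dtm_corpus: %d documents over %d slices (sizes: %s), %d words\n",
              length(x$documents), length(x$slice_sizes),
              paste(x$slice_sizes, collapse = ", "), length(x$vocabulary$words)))
  invisible(x)
}

#' Encode DEG records as a time-sliced corpus
#'
#' Groups flagged DEG records by (compound, time point) into one document
#' per condition. Each DEG becomes the word `<gene>_<direction>` with count
#' `round(100 * fold_change)` (half away from zero), floored at 1 token so
#' every retained DEG is represented. Documents are ordered slice-major:
#' all slice-0 documents first, compounds sorted within a slice.
#'
#' @param deg_records Records from [select_degs()]; only rows with
#'   `is_deg == TRUE` generate tokens. Conditions present in the records but
#'   left with no DEG yield empty documents (reported via `message()`).
#' @param vocabulary The [build_vocabulary()] universe; every record's gene
#'   must be present.
#' @param count_cap Optional upper bound applied to word counts
#'   (default `Inf`, no cap).
#' @return A `dtm_corpus`: `vocabulary`, `documents` (each with `doc_id`,
#'   `compound_id`, `time_point`, `slice_index`, 0-based `word_ids`,
#'   `counts`), `slice_sizes`, `slice_labels`, `doc_meta`.
#' @export
encode_documents <- function(deg_records, vocabulary, count_cap = Inf) {
  stopifnot(inherits(vocabulary, "dtm_vocabulary"))
  if (is.null(deg_records$is_deg)) .stopf("records lack is_deg; run select_degs() first")
  unknown <- setdiff(unique(deg_records$gene_id), vocabulary$gene_ids)
  if (length(unknown))
    .stopf("gene ids absent from vocabulary: %s",
           paste(utils::head(unknown, 5), collapse = ", "))
  if (any(deg_records$fold_change < 1))
    .stopf("internal invariant violated: fold_change < 1 (records must be direction-normalized)")

  slice_labels <- sort(unique(deg_records$time_point))
  compounds <- sort(unique(as.character(deg_records$compound_id)))
  degs <- deg_records[deg_records$is_deg, , drop = FALSE]
  key <- function(cpd, tp) paste(cpd, format(tp, trim = TRUE), sep = "@")
  deg_split <- split(degs, key(degs$compound_id, degs$time_point))

  # the (compound, time) grid actually present in the records, slice-major
  present <- unique(deg_records[, c("compound_id", "time_point")])
  documents <- vector("list", nrow(present))
  i <- 0L
  for (s in seq_along(slice_labels)) {
    tp <- slice_labels[s]
    for (cpd in compounds) {
      if (!any(present$compound_id == cpd & present$time_point == tp)) next
      i <- i + 1L
      grp <- deg_split[[key(cpd, tp)]]
      if (is.null(grp) || !nrow(grp)) {
        message(sprintf("no DEGs for compound '%s' at time %s: empty document",
                        cpd, format(tp)))
        word_ids <- integer(0)
        counts <- integer(0)
      } else {
        words <- paste0(grp$gene_id, "_", grp$direction)
        word_ids <- unname(vocabulary$index[words])
        counts <- pmax(1, pmin(count_cap, .round_half_up(100 * grp$fold_change)))
        o <- order(word_ids)
        word_ids <- as.integer(word_ids[o])
        counts <- as.integer(counts[o])
      }
      documents[[i]] <- list(doc_id = paste0(cpd, "_", format(tp, trim = TRUE)),
                             compound_id = cpd, time_point = tp,
                             slice_index = s - 1L,
                             word_ids = word_ids, counts = counts)
    }
  }
  .new_corpus(vocabulary, documents[seq_len(i)], slice_labels)
}

#' Build a corpus straight from an expression study
#'
#' Convenience wrapper running [compute_fold_changes()] for every
#' (compound, time point) cell, [select_degs()], and [encode_documents()].
#' A compound missing either dose group at any time point is dropped
#' entirely by default (with a warning), which keeps every slice populated
#' by the same compound set; set `keep_partial = TRUE` to keep the contrasts
#' that do exist.
#'
#' @param study An [expression_study()].
#' @param deg_threshold Log2 fold-change cutoff passed to [select_degs()].
#' @param keep_partial Keep compounds with incomplete time courses?
#' @param count_cap Passed to [encode_documents()].
#' @return A `dtm_corpus`.
#' @export
build_corpus <- function(study, deg_threshold = 1, keep_partial = FALSE,
                         count_cap = Inf) {
  stopifnot(inherits(study, "expression_study"))
  recs <- list()
  for (cpd in study$compounds) {
    cpd_recs <- list()
    complete <- TRUE
    for (tp in study$time_points) {
      r <- tryCatch(compute_fold_changes(study, cpd, tp), error = function(e) NULL)
      if (is.null(r)) complete <- FALSE else cpd_recs[[length(cpd_recs) + 1L]] <- r
    }
    if (!complete && !keep_partial) {
      .warnf("compound '%s' lacks a complete time course; dropped from the corpus", cpd)
      next
    }
    recs <- c(recs, cpd_recs)
  }
  if (!length(recs)) .stopf("no complete contrasts; corpus would be empty")
  records <- do.call(rbind, recs)
  records <- select_degs(records, deg_threshold)
  encode_documents(records, build_vocabulary(study$gene_ids), count_cap = count_cap)
}
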