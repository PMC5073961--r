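#' Write a corpus in LDA-C format
#'
#' Writes four plain-text files under `dir`:
#' \describe{
#'   \item{`<prefix>.ldac`}{one line per document, `U id1:cnt1 id2:cnt2 ...`
#'     with `U` the number of unique words and 0-based word ids;}
#'   \item{`<prefix>-seq.dat`}{first line the number of time slices, then one
#'     line per slice with its document count (documents in the `.ldac` file
#'     are slice-major);}
#'   \item{`<prefix>.vocab`}{one word per line, line number = word id
#'     (0-based);}
#'   \item{`<prefix>-docs.tsv`}{document metadata: `doc_id`, `compound_id`,
#'     `time_point`, `slice_index`.}
#' }
#'
#' @param corpus A `dtm_corpus`.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix, default `"corpus"`.
#' @return Invisibly, the named vector of file paths.
#' @export
write_corpus <- function(corpus, dir, prefix = "corpus") {
  stopifnot(inherits(corpus, "dtm_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ldac = file.path(dir, paste0(prefix, ".ldac")),
             seq = file.path(dir, paste0(prefix, "-seq.dat")),
             vocab = file.path(dir, paste0(prefix, ".vocab")),
             docs = file.path(dir, paste0(prefix, "-docs.tsv")))
  lines <- vapply(corpus$documents, function(d) {
    if (!length(d$word_ids)) return("0")
    paste(length(d$word_ids),
          paste0(d$word_ids, ":", d$counts, collapse = " "))
  }, character(1))
  writeLines(lines, paths["ldac"])
  writeLines(c(as.character(length(corpus$slice_sizes)),
               as.character(corpus$slice_sizes)), paths["seq"])
  writeLines(corpus$vocabulary$words, paths["vocab"])
  utils::write.table(corpus$doc_meta, paths["docs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Parse one LDA-C file into a list of (word_ids, counts) pairs, validating
# the unique-count prefix of every line.
.read_ldac_lines <- function(path) {
  if (!file.exists(path)) .stopf("corpus file not found: %s", path)
  lines <- readLines(path)
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (!length(parts) || is.na(suppressWarnings(u <- as.integer(parts[1]))))
      .stopf("%s line %d: missing unique-word count", path, i)
    pairs <- parts[-1]
    if (length(pairs) != u)
      .stopf("%s line %d: declares %d words but has %d id:count pairs",
             path, i, u, length(pairs))
    if (u == 0L) return(list(word_ids = integer(0), counts = integer(0)))
    split_ok <- regmatches(pairs, regexec("^([0-9]+):([0-9]+)$", pairs))
    bad <- which(lengths(split_ok) != 3L)
    if (length(bad))
      .stopf("%s line %d: malformed id:count pair '%s'", path, i, pairs[bad[1]])
    m <- matrix(as.integer(unlist(lapply(split_ok, `[`, 2:3))), ncol = 2, byrow = TRUE)
    if (any(m[, 2] < 1L)) .stopf("%s line %d: zero/negative count", path, i)
    list(word_ids = m[, 1], counts = m[, 2])
  })
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir Directory containing the files.
#' @param prefix File-name prefix, default `"corpus"`.
#' @return A `dtm_corpus`. If the metadata TSV is missing, documents get
#'   synthetic ids (`doc<i>`) and the slice index doubles as the time label.
#' @export
read_corpus <- function(dir, prefix = "corpus") {
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  docs_raw <- .read_ldac_lines(p(".ldac"))
  seq_lines <- readLines(p("-seq.dat"))
  n_slices <- as.integer(seq_lines[1])
  slice_sizes <- as.integer(seq_lines[1 + seq_len(n_slices)])
  if (anyNA(slice_sizes) || sum(slice_sizes) != length(docs_raw))
    .stopf("%s: slice sizes (%s) do not sum to the document count (%d)",
           p("-seq.dat"), paste(slice_sizes, collapse = "+"), length(docs_raw))
  words <- readLines(p(".vocab"))
  if (length(words) %% 2L != 0L)
    .stopf("%s: direction-split vocabulary must have an even word count", p(".vocab"))
  gene_ids <- sub("_(up|down)$", "", words[seq(1, length(words), by = 2)])
  vocab <- structure(list(words = words, gene_ids = gene_ids,
                          index = stats::setNames(seq_along(words) - 1L, words)),
                     class = "dtm_vocabulary")

  slice_of <- rep(seq_len(n_slices) - 1L, slice_sizes)
  meta_path <- p("-docs.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    if (nrow(meta) != length(docs_raw))
      .stopf("%s: %d metadata rows for %d documents", meta_path, nrow(meta), length(docs_raw))
  } else {
    meta <- data.frame(doc_id = paste0("doc", seq_along(docs_raw)),
                       compound_id = paste0("doc", seq_along(docs_raw)),
                       time_point = slice_of, slice_index = slice_of,
                       stringsAsFactors = FALSE)
  }
  slice_labels <- sort(unique(meta$time_point))
  if (length(slice_labels) != n_slices) slice_labels <- seq_len(n_slices) - 1
  documents <- lapply(seq_along(docs_raw), function(i) {
    d <- docs_raw[[i]]
    if (length(d$word_ids) && max(d$word_ids) >= length(words))
      .stopf("document %d references word id %d beyond the vocabulary (%d words)",
             i, max(d$word_ids), length(words))
    list(doc_id = as.character(meta$doc_id[i]),
         compound_id = as.character(meta$compound_id[i]),
         time_point = as.numeric(meta$time_point[i]),
         slice_index = slice_of[i],
         word_ids = d$word_ids, counts = d$counts)
  })
  .new_corpus(vocab, documents, slice_labels)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: set name, description, then member gene ids.
#'
#' @param path Path to the GMT file.
#' @param source Label recorded alongside the collection (e.g. `"KEGG"`).
#' @return An object of class `gene_set_collection`: named list `sets` of
#'   character vectors, `description` per set, and `source`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) .stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parsed) < 3L)
  if (length(short))
    .stopf("%s line %d: GMT lines need name, description and >=1 member",
           path, short[1])
  nm <- vapply(parsed, `[`, character(1), 1L)
  if (anyDuplicated(nm)) .stopf("%s: duplicate set name '%s'", path, nm[duplicated(nm)][1])
  sets <- lapply(parsed, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- which(!lengths(sets))
  if (length(empty)) .stopf("%s: set '%s' has no members", path, nm[empty[1]])
  structure(list(sets = stats::setNames(sets, nm),
                 description = stats::setNames(vapply(parsed, `[`, character(1), 2L), nm),
                 source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets (median size %d)\n",
              x$source, length(x$sets), as.integer(stats::median(lengths(x$sets)))))
  invisible(x)
}
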