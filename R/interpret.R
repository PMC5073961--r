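#' Hard topic assignment per document
#'
#' Assigns each compound-time document to the topic with the largest
#' posterior probability P(T|D); ties are broken by the lowest topic index
#' (reported via `message()`).
#'
#' @param fitted A [fit_dtm()] result (or any object with a normalized
#'   `doc_topic` matrix and `doc_meta`).
#' @return Data frame: `doc_id`, `compound_id`, `time_point`,
#'   `assigned_topic` (1-based index), `probability` (the winning entry),
#'   `margin` (gap to the runner-up).
#' @export
assign_topics <- function(fitted) {
  p <- fitted$doc_topic
  idx <- max.col(p, ties.method = "first")
  n_max <- rowSums(p == p[cbind(seq_len(nrow(p)), idx)])
  if (any(n_max > 1L))
    message(sprintf("%d document(s) had tied topic probabilities; lowest index kept",
                    sum(n_max > 1L)))
  top <- p[cbind(seq_len(nrow(p)), idx)]
  runner <- vapply(seq_len(nrow(p)), function(i) {
    if (ncol(p) == 1L) return(0) else max(p[i, -idx[i]])
  }, numeric(1))
  data.frame(doc_id = fitted$doc_meta$doc_id,
             compound_id = fitted$doc_meta$compound_id,
             time_point = fitted$doc_meta$time_point,
             assigned_topic = idx,
             probability = top,
             margin = top - runner,
             stringsAsFactors = FALSE)
}

#' Rank gene-words within one topic at one time slice
#'
#' Orders the vocabulary by the topic's word probability P(W|T) at the
#' given slice, descending; ties are broken by ascending word id, so the
#' ranking is fully deterministic.
#'
#' @param fitted A [fit_dtm()] result.
#' @param topic Topic index (1-based).
#' @param slice Slice index (1-based).
#' @return A `gene_ranking` data frame: `rank` (from 1), `word_id`
#'   (0-based), `word`, `probability`, plus `topic` and `slice` columns.
#' @export
rank_genes <- function(fitted, topic, slice) {
  K <- nrow(fitted$topic_word[[1]])
  T_ <- length(fitted$topic_word)
  if (topic < 1 || topic > K) .stopf("topic must be in 1..%d", K)
  if (slice < 1 || slice > T_) .stopf("slice must be in 1..%d", T_)
  p <- fitted$topic_word[[slice]][topic, ]
  o <- order(-p, seq_along(p))
  data.frame(topic = topic, slice = slice, rank = seq_along(p),
             word_id = o - 1L,
             word = fitted$vocabulary$words[o],
             probability = unname(p[o]),
             stringsAsFactors = FALSE)
}

#' Truncate a ranking to its top n words
#'
#' @param ranking A [rank_genes()] data frame.
#' @param n Number of words to keep (default 300, the conventional depth
#'   for per-slice functional analysis).
#' @return Character vector of the first `min(n, W)` words.
#' @export
top_n <- function(ranking, n = 300) {
  if (n < 1) .stopf("n must be >= 1")
  ranking$word[seq_len(min(n, nrow(ranking)))]
}

#' Representative words of a topic across all slices
#'
#' A word is representative of a topic if it ranks within the top `n` at
#' *every* time slice, i.e. the intersection over slices of the per-slice
#' top-`n` sets.
#'
#' @param fitted A [fit_dtm()] result.
#' @param topic Topic index (1-based).
#' @param n Per-slice rank cutoff (default 300).
#' @return Character vector of words (ordered as in slice 1's ranking).
#' @export
representative_genes <- function(fitted, topic, n = 300) {
  T_ <- length(fitted$topic_word)
  tops <- lapply(seq_len(T_), function(t) top_n(rank_genes(fitted, topic, t), n))
  Reduce(intersect, tops)
}

#' Per-word topic membership counts
#'
#' For each vocabulary word, counts the topics whose top-`n` list contains
#' it. With `per_slice = FALSE` (default) a word belongs to a topic if it
#' is in the top `n` at *any* slice; with `per_slice = TRUE` membership is
#' counted within each slice separately and a matrix is returned.
#'
#' @param fitted A [fit_dtm()] result.
#' @param n Rank cutoff (default 300).
#' @param per_slice Count per slice instead of any-slice membership?
#' @return Named integer vector over words (or words x slices matrix).
#' @export
topic_membership_counts <- function(fitted, n = 300, per_slice = FALSE) {
  K <- nrow(fitted$topic_word[[1]])
  T_ <- length(fitted$topic_word)
  words <- fitted$vocabulary$words
  if (per_slice) {
    out <- matrix(0L, length(words), T_, dimnames = list(words, NULL))
    for (t in seq_len(T_)) for (k in seq_len(K)) {
      top <- top_n(rank_genes(fitted, k, t), n)
      out[top, t] <- out[top, t] + 1L
    }
    return(out)
  }
  counts <- stats::setNames(integer(length(words)), words)
  for (k in seq_len(K)) {
    member <- unique(unlist(lapply(seq_len(T_), function(t)
      top_n(rank_genes(fitted, k, t), n))))
    counts[member] <- counts[member] + 1L
  }
  counts
}

#' Gene-set over-representation by Fisher's exact test
#'
#' Strips the `_up`/`_down` direction tags from a word list, collapses
#' duplicates to genes, and tests each gene set for over-representation
#' against a gene universe with the one-sided hypergeometric tail
#' (`P(X >= a)`), i.e. the one-sided Fisher's exact test. P-values are
#' Benjamini-Hochberg adjusted across the sets of the query.
#'
#' @param word_list Character vector of words (or plain gene ids).
#' @param collection A [read_gmt()] collection (or a named list of gene-id
#'   vectors).
#' @param universe Character vector of gene ids forming the universe; the
#'   query genes must be contained in it.
#' @return Data frame per set: `set`, the 2x2 counts `a` (list-and-set),
#'   `b` (list only), `c` (set only), `d` (neither), `odds_ratio`, `p_raw`,
#'   `p_adj`, ordered by `p_raw`.
#' @export
fisher_enrichment <- function(word_list, collection, universe) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  genes <- unique(sub("_(up|down)$", "", word_list))
  universe <- unique(as.character(universe))
  if (!length(universe)) .stopf("empty gene universe")
  if (!length(genes)) .stopf("empty query gene list")
  outside <- setdiff(genes, universe)
  if (length(outside))
    .stopf("query genes outside the universe: %s",
           paste(utils::head(outside, 5), collapse = ", "))
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    ks <- intersect(sets[[nm]], universe)
    if (!length(ks)) {
      .warnf("set '%s' has no members in the universe; skipped", nm)
      return(NULL)
    }
    a <- length(intersect(genes, ks))
    b <- n - a
    c_ <- length(ks) - a
    d <- N - length(ks) - b
    # one-sided upper tail of the hypergeometric: P(X >= a)
    p <- stats::phyper(a - 1, length(ks), N - length(ks), n, lower.tail = FALSE)
    or <- if (b == 0 || c_ == 0) Inf else (a * d) / (b * c_)
    data.frame(set = nm, a = a, b = b, c = c_, d = d,
               odds_ratio = or, p_raw = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) .stopf("no gene set overlaps the universe")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out[order(out$p_raw, out$set), , drop = FALSE]
}

#' Enrichment for every (topic, slice) top-n gene list
#'
#' Convenience loop running [fisher_enrichment()] on the top-`n` ranked
#' words of each topic at each slice; adjustment is within each
#' (topic, slice) query.
#'
#' @param fitted A [fit_dtm()] result.
#' @param collection A [read_gmt()] collection.
#' @param n Rank cutoff (default 300).
#' @param universe Gene universe; defaults to the corpus gene universe.
#' @return Data frame with `topic`, `slice`, `time_point` and the
#'   [fisher_enrichment()] columns.
#' @export
enrich_topics <- function(fitted, collection, n = 300,
                          universe = fitted$vocabulary$gene_ids) {
  K <- nrow(fitted$topic_word[[1]])
  T_ <- length(fitted$topic_word)
  out <- list()
  for (k in seq_len(K)) for (t in seq_len(T_)) {
    res <- fisher_enrichment(top_n(rank_genes(fitted, k, t), n),
                             collection, universe)
    res <- cbind(topic = k, slice = t,
                 time_point = fitted$slice_labels[t], res)
    out[[length(out) + 1L]] <- res
  }
  do.call(rbind, out)
}
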