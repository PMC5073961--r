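# Flatten a corpus into a token table: one row per (document, word) pair.
.corpus_nnz <- function(corpus) {
  docs <- corpus$documents
  nw <- vapply(docs, function(d) length(d$word_ids), integer(1))
  list(doc = rep.int(seq_along(docs), nw),
       word = unlist(lapply(docs, `[[`, "word_ids"), use.names = FALSE) + 1L, # 1-based
       slice = rep.int(vapply(docs, `[[`, integer(1), "slice_index"), nw) + 1L,
       count = as.numeric(unlist(lapply(docs, `[[`, "counts"), use.names = FALSE)),
       n_docs = length(docs),
       n_words = length(corpus$vocabulary$words),
       n_slices = length(corpus$slice_sizes))
}

# Mean-field document E-step shared by static LDA and the DTM.
#
# ltok: nnz x K matrix of expected log word probabilities per token row.
# Iterates phi/gamma to a fixed point; returns gamma (n_docs x K), phi
# (nnz x K) and the exact variational bound of the document side evaluated
# at (gamma, phi). Documents without tokens keep gamma = alpha and
# contribute zero bound.
.e_step_engine <- function(nnz, ltok, K, alpha, doc_tol, doc_max_iter,
                           gamma_init = NULL) {
  n_docs <- nnz$n_docs
  doc <- nnz$doc
  count <- nnz$count
  totals <- numeric(n_docs)
  agg0 <- rowsum(count, doc)
  present <- as.integer(rownames(agg0))
  totals[present] <- agg0[, 1]

  gamma <- if (is.null(gamma_init)) {
    matrix(alpha + totals / K, n_docs, K)
  } else gamma_init
  phi <- NULL
  lam <- NULL
  psidiff <- NULL
  for (it in seq_len(doc_max_iter)) {
    psidiff <- digamma(gamma) - digamma(rowSums(gamma))
    lam <- psidiff[doc, , drop = FALSE] + ltok
    lse <- .row_lse(lam)
    phi <- exp(lam - lse)
    agg <- rowsum(count * phi, doc)
    gamma_new <- matrix(alpha, n_docs, K)
    gamma_new[present, ] <- alpha + agg
    delta <- max(rowMeans(abs(gamma_new - gamma)))
    gamma <- gamma_new
    if (delta < doc_tol) break
  }
  # bound at (gamma, phi): theta terms use the updated gamma, token terms the
  # lambda that produced phi; the gamma = alpha + sum(c phi) identity cancels
  # the E[log theta] cross terms against the Dirichlet ones.
  lse <- .row_lse(lam)
  z_term <- sum(count * (lse - rowSums(phi * psidiff[doc, , drop = FALSE])))
  theta_term <- n_docs * (lgamma(K * alpha) - K * lgamma(alpha)) -
    sum(lgamma(rowSums(gamma))) + sum(lgamma(gamma))
  list(gamma = gamma, phi = phi, bound = theta_term + z_term, totals = totals)
}

# Best-of-two E-step: a warm start from the previous iteration's gamma
# guarantees coordinate ascent, but with sparse priors it can freeze early
# topic commitments; a cold restart escapes such fixed points. Running both
# and keeping the higher bound preserves monotone ascent while avoiding the
# trap. With no previous gamma the two coincide and the cold run is skipped.
.e_step_best <- function(nnz, ltok, K, alpha, doc_tol, doc_max_iter,
                         gamma_prev = NULL) {
  cold <- .e_step_engine(nnz, ltok, K, alpha, doc_tol, doc_max_iter)
  if (is.null(gamma_prev)) return(cold)
  warm <- .e_step_engine(nnz, ltok, K, alpha, doc_tol, doc_max_iter,
                         gamma_init = gamma_prev)
  if (warm$bound >= cold$bound) warm else cold
}

#' Fit a static (exchangeable) latent Dirichlet allocation model
#'
#' Variational EM with a symmetric Dirichlet document prior and
#' point-estimated topic-word distributions, pooling all time slices. Used
#' both to initialize the dynamic model and as the exchangeable baseline it
#' is compared against: LDA ignores slice structure entirely, so permuting
#' or reversing slices cannot change its fit.
#'
#' @param corpus A `dtm_corpus` (slices are ignored).
#' @param n_topics Number of topics K.
#' @param alpha Symmetric Dirichlet document-topic prior.
#' @param seed Integer seed for the random topic initialization.
#' @param max_iter,rel_tol EM iteration cap and relative-bound stopping rule.
#' @param doc_tol,doc_max_iter Per-document inner-loop controls (mean
#'   absolute change in gamma, iteration cap).
#' @return List with `topics` (K x W probabilities), `doc_topic`
#'   (normalized gamma), `gamma`, `bound_trace`, `converged`.
#' @export
fit_lda <- function(corpus, n_topics, alpha = 0.01, seed = 1,
                    max_iter = 60, rel_tol = 1e-5,
                    doc_tol = 1e-3, doc_max_iter = 100) {
  stopifnot(inherits(corpus, "dtm_corpus"), n_topics >= 1, alpha > 0)
  nnz <- .corpus_nnz(corpus)
  if (!length(nnz$doc)) .stopf("corpus has no tokens")
  K <- as.integer(n_topics)
  W <- nnz$n_words
  set.seed(seed)
  topics <- matrix(stats::rgamma(K * W, shape = 1), K, W)
  topics <- topics / rowSums(topics)

  bound_trace <- numeric(0)
  gamma <- NULL
  converged <- FALSE
  res <- NULL
  for (it in seq_len(max_iter)) {
    ltok <- t(log(topics)[, nnz$word, drop = FALSE])
    res <- .e_step_best(nnz, ltok, K, alpha, doc_tol, doc_max_iter,
                        gamma_prev = gamma)
    gamma <- res$gamma
    bound_trace <- c(bound_trace, res$bound)
    if (it > 1L) {
      prev <- bound_trace[it - 1L]
      if (abs(res$bound - prev) < rel_tol * abs(prev)) {
        converged <- TRUE
        break
      }
    }
    ew <- rowsum(nnz$count * res$phi, nnz$word)           # words x K
    topics <- matrix(.EPS, K, W)
    topics[, as.integer(rownames(ew))] <- t(ew) + .EPS
    topics <- topics / rowSums(topics)
  }
  list(topics = topics, doc_topic = gamma / rowSums(gamma), gamma = gamma,
       bound_trace = bound_trace, converged = converged)
}

#' Evaluate the static-LDA variational bound at fixed topics
#'
#' Runs the document E-step to convergence with the topic-word
#' distributions held fixed and returns the resulting bound. This scores
#' any set of topics -- e.g. those implied by a dynamic fit on a
#' single-slice corpus -- on the common static objective.
#'
#' @param corpus A `dtm_corpus`.
#' @param topics K x W matrix of topic-word probabilities (rows sum to 1).
#' @param alpha Symmetric Dirichlet document-topic prior.
#' @param doc_tol,doc_max_iter Inner-loop controls.
#' @return Scalar variational bound.
#' @export
lda_bound <- function(corpus, topics, alpha = 0.01,
                      doc_tol = 1e-4, doc_max_iter = 200) {
  nnz <- .corpus_nnz(corpus)
  K <- nrow(topics)
  ltok <- t(log(pmax(topics, .EPS))[, nnz$word, drop = FALSE])
  .e_step_engine(nnz, ltok, K, alpha, doc_tol, doc_max_iter)$bound
}

#' Initialize topic chains from a pooled static LDA fit
#'
#' Fits an exchangeable LDA on the slice-pooled corpus — with
#' `config$init_starts` random restarts, keeping the start with the best
#' static bound — and replicates the log of each (floored, renormalized)
#' topic across all slices as the initial variational observations of its
#' chain. Restart seeds are derived from `config$seed`, so initialization
#' is deterministic given the seed.
#'
#' @param corpus A `dtm_corpus`.
#' @param config A [dtm_config()].
#' @return List of K matrices (`T x W`) of initial variational observations,
#'   with the winning LDA fit attached as attribute `"lda"`.
#' @export
lda_init <- function(corpus, config) {
  if (!length(corpus$documents)) .stopf("empty corpus")
  if (config$n_topics > length(corpus$documents))
    .warnf("more topics (%d) than documents (%d)", config$n_topics,
           length(corpus$documents))
  lda <- NULL
  for (s in seq_len(config$init_starts) - 1L) {
    cand <- fit_lda(corpus, config$n_topics, alpha = config$alpha,
                    seed = config$seed + s * 1000003L,
                    max_iter = config$lda_init_iter,
                    doc_tol = config$doc_tol,
                    doc_max_iter = config$doc_max_iter)
    if (is.null(lda) ||
        utils::tail(cand$bound_trace, 1) > utils::tail(lda$bound_trace, 1))
      lda <- cand
  }
  T_ <- length(corpus$slice_sizes)
  topics <- pmax(lda$topics, .EPS)
  topics <- topics / rowSums(topics)
  chains <- lapply(seq_len(config$n_topics), function(k) {
    matrix(log(topics[k, ]), T_, ncol(topics), byrow = TRUE)
  })
  attr(chains, "lda") <- lda
  chains
}
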