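#' Configuration for a dynamic topic model fit
#'
#' @param n_topics Number of topics K (default 20).
#' @param alpha Symmetric Dirichlet prior on document-topic mixtures
#'   (default 0.01; smaller values concentrate each document on fewer
#'   topics).
#' @param chain_var Transition variance of the Gaussian random walk linking
#'   a topic's natural parameters across consecutive slices (default 0.005;
#'   smaller values make per-slice word distributions more similar).
#' @param init_var Variance of the slice-1 prior around 0. Default
#'   `1000 * chain_var`: a diffuse anchor so the first slice is essentially
#'   data-driven, following the convention of the reference DTM
#'   implementation.
#' @param obs_var Variance of the variational observations (default 0.5,
#'   the reference-implementation convention); held fixed, not optimized.
#' @param em_max_iter,em_rel_tol Outer variational-EM cap and relative-ELBO
#'   stopping rule.
#' @param doc_max_iter,doc_tol Per-document inner loop: iteration cap and
#'   tolerance on the mean absolute change in gamma.
#' @param chain_max_iter Gradient-ascent iterations per topic per M-step.
#' @param lda_init_iter EM iterations of the pooled static LDA used for
#'   initialization.
#' @param init_starts Random restarts of the LDA initialization; the start
#'   with the best static bound seeds the chains. Restart seeds are derived
#'   deterministically from `seed`.
#' @param seed Integer seed; the only randomness is the LDA initialization,
#'   so the whole fit is reproducible from it.
#' @return An object of class `dtm_config`.
#' @export
dtm_config <- function(n_topics = 20, alpha = 0.01, chain_var = 0.005,
                       init_var = 1000 * chain_var, obs_var = 0.5,
                       em_max_iter = 50, em_rel_tol = 1e-4,
                       doc_max_iter = 100, doc_tol = 1e-3,
                       chain_max_iter = 15, lda_init_iter = 40, seed = 1,
                       init_starts = 4) {
  cfg <- list(n_topics = as.integer(n_topics), alpha = as.numeric(alpha),
              chain_var = as.numeric(chain_var),
              init_var = as.numeric(init_var), obs_var = as.numeric(obs_var),
              em_max_iter = as.integer(em_max_iter),
              em_rel_tol = as.numeric(em_rel_tol),
              doc_max_iter = as.integer(doc_max_iter),
              doc_tol = as.numeric(doc_tol),
              chain_max_iter = as.integer(chain_max_iter),
              lda_init_iter = as.integer(lda_init_iter),
              seed = as.integer(seed),
              init_starts = as.integer(init_starts))
  if (cfg$n_topics < 1L) .stopf("n_topics must be >= 1")
  if (cfg$init_starts < 1L) .stopf("init_starts must be >= 1")
  if (cfg$alpha <= 0) .stopf("alpha must be positive")
  if (cfg$chain_var <= 0 || cfg$init_var <= 0 || cfg$obs_var <= 0)
    .stopf("variances must be positive")
  if (cfg$em_rel_tol <= 0 || cfg$doc_tol <= 0) .stopf("tolerances must be positive")
  structure(cfg, class = "dtm_config")
}

#' Map chain natural parameters to word probabilities
#'
#' Uses the expected-exponential form of the variational bound:
#' `pi_w` is proportional to `exp(m_w + V_w / 2)`, computed in log space
#' with max-subtraction, so the result is shift-invariant in the means and
#' sums to exactly 1.
#'
#' @param mean Vector of (smoothed) natural-parameter means over words.
#' @param variance Vector (or scalar) of matching variances; zero is
#'   allowed and gives the plain softmax.
#' @return Probability vector over words.
#' @export
softmax_probs <- function(mean, variance = 0) {
  x <- mean + rep_len(variance, length(mean)) / 2
  if (any(!is.finite(x))) .stopf("non-finite natural parameters")
  e <- exp(x - max(x))
  e / sum(e)
}

#' Variational posterior for a single document
#'
#' Runs the mean-field fixed point for one document against the expected
#' log word probabilities of its time slice: responsibilities
#' `phi[n, k] ~ exp(digamma(gamma_k) + E[log pi_{t,k,w_n}])` and
#' `gamma_k = alpha + sum_n c_n phi[n, k]`, iterated until the mean absolute
#' change in gamma drops below `doc_tol`. A document with no tokens keeps
#' the prior as its posterior and contributes zero bound.
#'
#' @param doc A corpus document (`word_ids`, `counts`).
#' @param expected_log_topics K x U matrix of expected log word
#'   probabilities, columns aligned with `doc$word_ids`, taken at the
#'   document's slice.
#' @param alpha Symmetric Dirichlet prior.
#' @param doc_tol,doc_max_iter Convergence controls.
#' @return List with `gamma` (length K), `phi` (U x K), `bound`.
#' @export
doc_e_step <- function(doc, expected_log_topics, alpha = 0.01,
                       doc_tol = 1e-3, doc_max_iter = 100) {
  K <- nrow(expected_log_topics)
  U <- length(doc$word_ids)
  if (U == 0L) {
    message(sprintf("document '%s' has no tokens: posterior equals the prior",
                    if (!is.null(doc$doc_id)) doc$doc_id else "<unnamed>"))
    return(list(gamma = rep(alpha, K), phi = matrix(0, 0, K), bound = 0))
  }
  nnz <- list(doc = rep.int(1L, U), word = seq_len(U),
              count = as.numeric(doc$counts), n_docs = 1L)
  res <- .e_step_engine(nnz, t(expected_log_topics), K, alpha,
                        doc_tol, doc_max_iter)
  list(gamma = drop(res$gamma), phi = res$phi, bound = res$bound)
}

# --- per-topic chain objective -------------------------------------------
#
# F(beta_hat) = sum(E * m_tilde) - sum_t n_t * log zeta_t + prior(m_tilde)
# with m_tilde = S beta_hat,
#      log zeta_t = logsumexp_w(m_tilde[t, ] + V_tilde[t] / 2),
#      prior(m) = -sum_w m[1,w]^2 / (2 v1)
#                 - sum_{t>1} sum_w (m[t,w] - m[t-1,w])^2 / (2 chain_var),
#      v1 = init_var + chain_var.
# The smoothed variances V_tilde do not depend on beta_hat (fixed obs_var),
# so F is a smooth concave function of beta_hat; it is maximized by gradient
# ascent with a backtracking line search, which guarantees monotone ascent.

.chain_objective <- function(m_tilde, E_counts, slice_totals, V_tilde,
                             chain_var, v1) {
  T_ <- nrow(m_tilde)
  logzeta <- V_tilde / 2 + apply(m_tilde, 1, log_sum_exp)
  val <- sum(E_counts * m_tilde) - sum(slice_totals * logzeta) -
    sum(m_tilde[1, ]^2) / (2 * v1)
  if (T_ > 1L) {
    d <- m_tilde[-1, , drop = FALSE] - m_tilde[-T_, , drop = FALSE]
    val <- val - sum(d^2) / (2 * chain_var)
  }
  list(value = val, logzeta = logzeta)
}

.chain_gradient_m <- function(m_tilde, E_counts, slice_totals, logzeta,
                              V_tilde, chain_var, v1) {
  T_ <- nrow(m_tilde)
  pi_tilde <- exp(m_tilde + V_tilde / 2 - logzeta)
  g <- E_counts - slice_totals * pi_tilde
  g[1, ] <- g[1, ] - m_tilde[1, ] / v1
  if (T_ > 1L) {
    d <- (m_tilde[-1, , drop = FALSE] - m_tilde[-T_, , drop = FALSE]) / chain_var
    g[-1, ] <- g[-1, ] - d
    g[-T_, ] <- g[-T_, ] + d
  }
  g
}

#' M-step update of one topic chain
#'
#' Given the expected word counts assigned to a topic in each slice,
#' re-estimates the chain's variational observations by gradient ascent
#' (with backtracking line search) on the per-topic bound, re-running the
#' Kalman smoother implicitly through the linear smoother map at every
#' step. The softmax normalizer is handled through the per-slice auxiliary
#' bound variable `zeta_t = sum_w exp(m_tilde + V_tilde / 2)`.
#'
#' @param chain List with element `beta_hat` (`T x W` variational
#'   observations); as returned by [lda_init()] elements wrapped via
#'   `list(beta_hat = .)`, or a previous update.
#' @param expected_counts `T x W` matrix of expected counts
#'   (`sum_d c * phi` per slice).
#' @param config A [dtm_config()].
#' @return List with `beta_hat`, `m_tilde`, `V_tilde`, `logzeta`, `bound`
#'   (the per-topic objective after the update) and `bound_before`.
#' @export
update_topic_chain <- function(chain, expected_counts, config) {
  beta_hat <- chain$beta_hat
  T_ <- nrow(beta_hat)
  if (any(expected_counts < 0)) .stopf("expected counts must be non-negative")
  slice_totals <- rowSums(expected_counts)
  v1 <- config$init_var + config$chain_var
  ks <- kalman_smooth(beta_hat, config$obs_var, config$chain_var, config$init_var)
  S <- .smoother_matrix(T_, config$obs_var, config$chain_var, config$init_var)
  V_tilde <- ks$V_tilde

  m_tilde <- ks$m_tilde
  obj <- .chain_objective(m_tilde, expected_counts, slice_totals, V_tilde,
                          config$chain_var, v1)
  if (!is.finite(obj$value))
    .stopf("non-finite chain bound before update (slice totals: %s)",
           paste(signif(slice_totals, 3), collapse = ", "))
  bound_before <- obj$value
  step <- 1 / (max(slice_totals) + 1 / config$chain_var)
  for (it in seq_len(config$chain_max_iter)) {
    g_m <- .chain_gradient_m(m_tilde, expected_counts, slice_totals,
                             obj$logzeta, V_tilde, config$chain_var, v1)
    grad <- crossprod(S, g_m)                 # t(S) %*% g_m
    improved <- FALSE
    for (bt in seq_len(40L)) {
      cand <- beta_hat + step * grad
      m_cand <- S %*% cand
      obj_cand <- .chain_objective(m_cand, expected_counts, slice_totals,
                                   V_tilde, config$chain_var, v1)
      if (is.finite(obj_cand$value) && obj_cand$value >= obj$value) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    gain <- obj_cand$value - obj$value
    beta_hat <- cand
    m_tilde <- m_cand
    obj <- obj_cand
    if (bt == 1L) step <- step * 1.8
    if (gain < 1e-9 * (abs(obj$value) + 1)) break
  }
  if (!all(is.finite(obj$value)))
    .stopf("non-finite chain bound after update")
  list(beta_hat = beta_hat, m_tilde = m_tilde, V_tilde = V_tilde,
       logzeta = obj$logzeta, bound = obj$value, bound_before = bound_before)
}

# Constant part of a chain's ELBO contribution: variance terms of the
# Gaussian prior plus the entropy of the (marginal) smoothed posterior.
# Cross-slice posterior covariances are dropped, as in the reference DTM
# bound; these terms do not depend on beta_hat and so never affect the
# optimization, only the reported ELBO level.
.chain_bound_const <- function(V_tilde, W, chain_var, v1) {
  T_ <- length(V_tilde)
  val <- -W * V_tilde[1] / (2 * v1) - W * log(2 * pi * v1) / 2
  if (T_ > 1L) {
    val <- val - W * sum(V_tilde[-1] + V_tilde[-T_]) / (2 * chain_var) -
      (T_ - 1) * W * log(2 * pi * chain_var) / 2
  }
  val + sum(W * log(2 * pi * exp(1) * V_tilde) / 2)
}

#' Fit a dynamic topic model
#'
#' Variational EM for a topic model whose K topic-word distributions drift
#' across time slices through a Gaussian random walk on natural parameters.
#' Documents are modeled per slice with a symmetric-Dirichlet LDA whose
#' topics are the slice's softmax-transformed chain states; chains are
#' inferred with a variational Kalman forward filter and backward smoother.
#' Initialization pools all slices into a static LDA ([lda_init()]); the
#' E-step ([doc_e_step()] over all documents) and the M-step
#' ([update_topic_chain()] per topic) alternate until the relative ELBO
#' change falls below `em_rel_tol`.
#'
#' @param corpus A `dtm_corpus`.
#' @param config A [dtm_config()].
#' @return An object of class `fitted_dtm`: `doc_topic` (documents x K,
#'   rows sum to 1, i.e. P(T|D)), `topic_word` (list over slices of K x W
#'   matrices, rows sum to 1, i.e. P(W|T)_t), `gamma`, `elbo_trace`,
#'   `converged`, `chains`, `config`, plus the corpus `vocabulary`,
#'   `doc_meta` and `slice_labels`.
#' @export
fit_dtm <- function(corpus, config = dtm_config()) {
  stopifnot(inherits(corpus, "dtm_corpus"), inherits(config, "dtm_config"))
  T_ <- length(corpus$slice_sizes)
  if (T_ < 1L) .stopf("corpus has no slices")
  K <- config$n_topics
  nnz <- .corpus_nnz(corpus)
  if (!length(nnz$doc)) .stopf("corpus has no tokens")
  W <- nnz$n_words
  v1 <- config$init_var + config$chain_var

  init <- lda_init(corpus, config)
  # initialize chain states by smoothing the LDA observations (no M-step yet)
  chains <- lapply(init, function(b) {
    ks <- kalman_smooth(b, config$obs_var, config$chain_var, config$init_var)
    logzeta <- ks$V_tilde / 2 + apply(ks$m_tilde, 1, log_sum_exp)
    list(beta_hat = b, m_tilde = ks$m_tilde, V_tilde = ks$V_tilde,
         logzeta = logzeta)
  })
  V_tilde <- chains[[1]]$V_tilde

  # column-major index of each token's (slice, word) cell in a T x W matrix,
  # for expected-count aggregation
  cell <- (nnz$word - 1L) * T_ + nnz$slice
  elbo_trace <- numeric(0)
  gamma <- NULL
  converged <- FALSE
  for (iter in seq_len(config$em_max_iter)) {
    # E-step: expected log word probabilities per token, all topics at once
    ltok <- matrix(0, length(nnz$doc), K)
    for (k in seq_len(K)) {
      ell <- chains[[k]]$m_tilde - chains[[k]]$logzeta
      ltok[, k] <- ell[cbind(nnz$slice, nnz$word)]
    }
    res <- .e_step_best(nnz, ltok, K, config$alpha, config$doc_tol,
                        config$doc_max_iter, gamma_prev = gamma)
    gamma <- res$gamma

    elbo <- res$bound +
      K * .chain_bound_const(V_tilde, W, config$chain_var, v1)
    for (k in seq_len(K)) {
      obj <- .chain_objective(chains[[k]]$m_tilde, matrix(0, T_, W),
                              numeric(T_), V_tilde, config$chain_var, v1)
      elbo <- elbo + obj$value
    }
    elbo_trace <- c(elbo_trace, elbo)
    if (iter > 1L &&
        abs(elbo - elbo_trace[iter - 1L]) <
          config$em_rel_tol * abs(elbo_trace[iter - 1L])) {
      converged <- TRUE
      break
    }
    if (iter == config$em_max_iter) break

    # M-step: per-topic expected counts, then chain updates
    for (k in seq_len(K)) {
      v <- rowsum(nnz$count * res$phi[, k], cell)
      E_k <- matrix(0, T_, W)
      E_k[as.integer(rownames(v))] <- v[, 1]
      chains[[k]] <- update_topic_chain(chains[[k]], E_k, config)
    }
  }
  if (!converged)
    .warnf("EM stopped at em_max_iter = %d without meeting em_rel_tol", config$em_max_iter)

  doc_topic <- gamma / rowSums(gamma)
  rownames(doc_topic) <- corpus$doc_meta$doc_id
  topic_word <- lapply(seq_len(T_), function(t) {
    m <- do.call(rbind, lapply(chains, function(ch)
      softmax_probs(ch$m_tilde[t, ], ch$V_tilde[t])))
    colnames(m) <- corpus$vocabulary$words
    m
  })
  structure(list(doc_topic = doc_topic, topic_word = topic_word,
                 gamma = gamma, elbo_trace = elbo_trace, converged = converged,
                 chains = chains, config = config,
                 vocabulary = corpus$vocabulary, doc_meta = corpus$doc_meta,
                 slice_labels = corpus$slice_labels),
            class = "fitted_dtm")
}

#' @export
print.fitted_dtm <- function(x, ...) {
  cat(sprintf("fitted_dtm: %d topics, %d documents, %d slices, %d words\n",
              x$config$n_topics, nrow(x$doc_topic), length(x$topic_word),
              ncol(x$topic_word[[1]])))
  cat(sprintf("  ELBO %.2f after %d iterations (converged: %s)\n",
              utils::tail(x$elbo_trace, 1), length(x$elbo_trace), x$converged))
  invisible(x)
}
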