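# Fixtures are built in code; nothing is read from disk.

# Deterministic two-compound, two-time study with hand-set contrasts:
# per (compound, time), treated-minus-control log2 shifts are exact so fold
# changes are known in closed form.
make_exact_study <- function(shifts, genes = paste0("g", seq_len(nrow(shifts))),
                             replicates = 2) {
  # shifts: genes x conditions matrix of log2 differences; condition names
  # "<compound>@<time>" define the design.
  conds <- strsplit(colnames(shifts), "@", fixed = TRUE)
  meta <- list()
  vals <- list()
  base <- 6
  for (j in seq_along(conds)) {
    cpd <- conds[[j]][1]
    tp <- as.numeric(conds[[j]][2])
    for (dg in c("control", "treated")) for (r in seq_len(replicates)) {
      id <- sprintf("%s_%s_%s_r%d", cpd, tp, dg, r)
      meta[[id]] <- data.frame(sample_id = id, compound_id = cpd,
                               time_point = tp, dose_group = dg,
                               replicate = r, stringsAsFactors = FALSE)
      vals[[id]] <- base + if (dg == "treated") shifts[, j] else 0
    }
  }
  expression_study(do.call(cbind, vals), do.call(rbind, meta), genes)
}

# Random replicate study for oracle comparisons.
make_random_study <- function(n_genes = 12, n_compounds = 2, times = c(4, 8),
                              replicates = 3, seed = 101) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  meta <- expand.grid(replicate = seq_len(replicates),
                      dose_group = c("control", "treated"),
                      time_point = times,
                      compound_id = sprintf("c%d", seq_len(n_compounds)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("s%03d", seq_len(nrow(meta)))
  vals <- matrix(rnorm(n_genes * nrow(meta), 7, 1), n_genes)
  colnames(vals) <- meta$sample_id
  expression_study(vals, meta[, c("sample_id", "compound_id", "time_point",
                                  "dose_group", "replicate")], genes)
}

# Dense multivariate-Gaussian oracle for the chain posterior: build the
# tridiagonal prior precision explicitly, add the observation precision and
# condition by direct inversion.
dense_chain_posterior <- function(beta_hat, nu_hat, chain_var, init_var) {
  T_ <- length(beta_hat)
  nu_hat <- rep_len(nu_hat, T_)
  v1 <- init_var + chain_var
  Q <- matrix(0, T_, T_)
  Q[1, 1] <- 1 / v1
  if (T_ > 1) for (t in 2:T_) {
    Q[t, t] <- Q[t, t] + 1 / chain_var
    Q[t - 1, t - 1] <- Q[t - 1, t - 1] + 1 / chain_var
    Q[t - 1, t] <- Q[t - 1, t] - 1 / chain_var
    Q[t, t - 1] <- Q[t, t - 1] - 1 / chain_var
  }
  post_prec <- Q + diag(1 / nu_hat, T_)
  Sigma <- solve(post_prec)
  list(mean = drop(Sigma %*% (beta_hat / nu_hat)), var = diag(Sigma))
}

# Wrap raw matrices as a fitted model so interpretation ops can be tested
# against hand-built posteriors.
make_fake_fitted <- function(doc_topic, topic_word, words = NULL) {
  if (is.matrix(topic_word)) topic_word <- list(topic_word)
  if (is.null(words)) {
    ng <- ncol(topic_word[[1]]) / 2
    words <- as.vector(rbind(paste0("g", seq_len(ng), "_up"),
                             paste0("g", seq_len(ng), "_down")))
  }
  topic_word <- lapply(topic_word, function(m) { colnames(m) <- words; m })
  gene_ids <- unique(sub("_(up|down)$", "", words))
  vocab <- structure(list(words = words, gene_ids = gene_ids,
                          index = stats::setNames(seq_along(words) - 1L, words)),
                     class = "dtm_vocabulary")
  n <- nrow(doc_topic)
  structure(list(doc_topic = doc_topic, topic_word = topic_word,
                 vocabulary = vocab,
                 doc_meta = data.frame(doc_id = paste0("d", seq_len(n)),
                                       compound_id = paste0("c", seq_len(n)),
                                       time_point = 1,
                                       slice_index = 0L,
                                       stringsAsFactors = FALSE),
                 slice_labels = seq_along(topic_word)),
            class = "fitted_dtm")
}

# Total variation distance between two probability vectors.
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Mean total-variation distance between consecutive-slice word
# distributions, averaged over topics and slice pairs.
mean_consecutive_tv <- function(fit) {
  T_ <- length(fit$topic_word)
  K <- nrow(fit$topic_word[[1]])
  vals <- c()
  for (t in seq_len(T_ - 1)) for (k in seq_len(K))
    vals <- c(vals, tv_dist(fit$topic_word[[t]][k, ], fit$topic_word[[t + 1]][k, ]))
  mean(vals)
}

# Reverse the slice order of a corpus (documents re-blocked slice-major).
reverse_corpus_slices <- function(corpus) {
  T_ <- length(corpus$slice_sizes)
  ord <- order(-corpus$doc_meta$slice_index)
  docs <- lapply(ord, function(i) {
    d <- corpus$documents[[i]]
    d$slice_index <- (T_ - 1L) - d$slice_index
    d
  })
  out <- corpus
  out$documents <- docs
  out$slice_sizes <- rev(corpus$slice_sizes)
  out$doc_meta <- data.frame(
    doc_id = vapply(docs, `[[`, character(1), "doc_id"),
    compound_id = vapply(docs, `[[`, character(1), "compound_id"),
    time_point = vapply(docs, `[[`, numeric(1), "time_point"),
    slice_index = vapply(docs, `[[`, integer(1), "slice_index"),
    stringsAsFactors = FALSE)
  out
}
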