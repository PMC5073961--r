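test_that("softmax of natural parameters is shift-invariant and exact on closed forms", {
  expect_equal(softmax_probs(rep(0, 4)), rep(0.25, 4))
  expect_equal(softmax_probs(log(1:3)), (1:3) / 6, tolerance = 1e-14)
  m <- rnorm(10)
  expect_equal(softmax_probs(m + 42), softmax_probs(m), tolerance = 1e-12)
  v <- runif(10)
  expect_equal(sum(softmax_probs(m, v)), 1, tolerance = 1e-12)
  # uniform variances cancel exactly like a mean shift
  expect_equal(softmax_probs(m, 0.7), softmax_probs(m), tolerance = 1e-12)
})

test_that("single-topic document posterior collapses to alpha + token count", {
  doc <- list(doc_id = "d", word_ids = c(0L, 2L), counts = c(3L, 4L))
  elt <- matrix(log(c(0.5, 0.5)), 1)   # K = 1 over the doc's two words
  post <- doc_e_step(doc, elt, alpha = 0.1)
  expect_equal(post$gamma, 0.1 + 7)
  expect_true(all(post$phi == 1))
})

test_that("gamma conservation holds: sum(gamma) = K alpha + token total", {
  set.seed(61)
  for (i in 1:10) {
    U <- sample(2:8, 1); K <- sample(2:4, 1)
    doc <- list(word_ids = seq_len(U) - 1L, counts = sample(1:50, U, TRUE))
    elt <- matrix(log(.Machine$double.eps + matrix(runif(K * U), K)), K)
    post <- doc_e_step(doc, elt, alpha = 0.05)
    expect_equal(sum(post$gamma), K * 0.05 + sum(doc$counts), tolerance = 1e-9)
  }
})

test_that("mirror-symmetric topics and a palindromic document give equal gamma", {
  p <- c(0.4, 0.3, 0.2, 0.1)
  elt <- rbind(log(p), log(rev(p)))
  doc <- list(word_ids = 0:3, counts = c(6L, 2L, 2L, 6L))
  post <- doc_e_step(doc, elt, alpha = 0.05, doc_tol = 1e-10)
  expect_equal(post$gamma[1], post$gamma[2], tolerance = 1e-6)
  # numerically confirmed against the label-swapped run
  swapped <- doc_e_step(doc, elt[2:1, ], alpha = 0.05, doc_tol = 1e-10)
  expect_equal(post$gamma, rev(swapped$gamma), tolerance = 1e-8)
})

test_that("a token-free document keeps its prior and contributes no bound", {
  expect_message(post <- doc_e_step(list(doc_id = "empty", word_ids = integer(0),
                                         counts = integer(0)),
                                    matrix(0, 2, 0), alpha = 0.3),
                 "prior")
  expect_equal(post$gamma, c(0.3, 0.3))
  expect_equal(post$bound, 0)
})

test_that("chain update with zero expected counts relaxes toward the prior", {
  cfg <- dtm_config(n_topics = 1, chain_var = 0.05, seed = 1)
  beta0 <- matrix(rnorm(3 * 10, sd = 2), 3, 10)
  up <- update_topic_chain(list(beta_hat = beta0), matrix(0, 3, 10), cfg)
  before <- kalman_smooth(beta0, cfg$obs_var, cfg$chain_var, cfg$init_var)$m_tilde
  expect_lt(mean(abs(up$m_tilde)), mean(abs(before)))
  expect_gte(up$bound, up$bound_before - 1e-6 * abs(up$bound_before))
})

test_that("single-slice chain update recovers the multinomial MLE", {
  set.seed(71)
  counts <- matrix(round(runif(30, 50, 2000)), 1, 30)
  cfg <- dtm_config(n_topics = 1, chain_var = 0.005, chain_max_iter = 200, seed = 1)
  init <- matrix(log(rep(1 / 30, 30)), 1, 30)
  up <- update_topic_chain(list(beta_hat = init), counts, cfg)
  pi_hat <- softmax_probs(up$m_tilde[1, ], up$V_tilde[1])
  expect_lt(tv_dist(pi_hat, counts[1, ] / sum(counts)), 1e-3)
})

test_that("chain updates never decrease the per-topic bound", {
  set.seed(72)
  cfg <- dtm_config(n_topics = 1, seed = 1)
  for (i in 1:5) {
    T_ <- sample(1:4, 1); W <- sample(5:40, 1)
    beta0 <- matrix(rnorm(T_ * W), T_, W)
    E <- matrix(rpois(T_ * W, 5), T_, W)
    up <- update_topic_chain(list(beta_hat = beta0), E, cfg)
    expect_gte(up$bound, up$bound_before - 1e-6 * abs(up$bound_before))
  }
})

test_that("fitting is reproducible from the seed and rows stay normalized", {
  sim <- generate_dtm_corpus(dtm_sim_spec(n_topics = 2, n_words = 30,
                                          n_slices = 3, docs_per_slice = 10,
                                          tokens_mean = 40, seed = 6))
  cfg <- dtm_config(n_topics = 2, alpha = 0.05, em_max_iter = 10, seed = 4)
  f1 <- suppressWarnings(fit_dtm(sim$corpus, cfg))
  f2 <- suppressWarnings(fit_dtm(sim$corpus, cfg))
  expect_identical(f1$doc_topic, f2$doc_topic)
  expect_identical(f1$topic_word, f2$topic_word)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  expect_lt(max(abs(rowSums(f1$doc_topic) - 1)), 1e-9)
  for (t in seq_along(f1$topic_word))
    expect_lt(max(abs(rowSums(f1$topic_word[[t]]) - 1)), 1e-9)
})

test_that("slice order matters to the dynamic fit but not to pooled LDA", {
  # drifting topics: initial spread and per-slice drift on comparable scales
  sim <- generate_dtm_corpus(dtm_sim_spec(n_topics = 2, n_words = 60,
                                          n_slices = 4, docs_per_slice = 30,
                                          tokens_mean = 80, chain_var = 0.5,
                                          init_var = 2, seed = 9))
  rev_corpus <- reverse_corpus_slices(sim$corpus)
  cfg <- dtm_config(n_topics = 2, alpha = 0.05, chain_var = 0.5,
                    em_max_iter = 30, seed = 4)
  fwd <- suppressWarnings(fit_dtm(sim$corpus, cfg))
  rev <- suppressWarnings(fit_dtm(rev_corpus, cfg))
  # slice 1 now holds different data, and the fitted distributions move
  diff_tv <- max(vapply(1:2, function(k)
    tv_dist(fwd$topic_word[[1]][k, ], rev$topic_word[[1]][k, ]), numeric(1)))
  expect_gt(diff_tv, 0.01)
  # the exchangeable model cannot see the reversal
  l1 <- fit_lda(sim$corpus, 2, alpha = 0.05, seed = 4)
  l2 <- fit_lda(rev_corpus, 2, alpha = 0.05, seed = 4)
  expect_equal(l1$topics, l2$topics, tolerance = 1e-12)
})

test_that("pooled single-topic LDA recovers the corpus word frequencies", {
  sim <- generate_dtm_corpus(dtm_sim_spec(n_topics = 2, n_words = 20,
                                          n_slices = 2, docs_per_slice = 8,
                                          tokens_mean = 30, seed = 10))
  lda <- fit_lda(sim$corpus, 1, alpha = 0.05, seed = 1, max_iter = 3)
  freq <- numeric(20)
  for (d in sim$corpus$documents)
    freq[d$word_ids + 1] <- freq[d$word_ids + 1] + d$counts
  expect_equal(drop(lda$topics), freq / sum(freq), tolerance = 1e-9)
})

test_that("LDA initialization is seed-deterministic with no zero entries", {
  sim <- generate_dtm_corpus(dtm_sim_spec(n_topics = 2, n_words = 20,
                                          n_slices = 2, docs_per_slice = 8,
                                          tokens_mean = 30, seed = 11))
  cfg <- dtm_config(n_topics = 3, alpha = 0.05, lda_init_iter = 5, seed = 2)
  c1 <- lda_init(sim$corpus, cfg)
  c2 <- lda_init(sim$corpus, cfg)
  expect_identical(c1[[1]], c2[[1]])
  expect_true(all(is.finite(unlist(c1))))  # epsilon floor: log never -Inf
})
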