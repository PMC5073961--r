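#' Topic-recovery benchmark on a simulated DTM corpus
#'
#' Forward-samples a corpus with known topic chains, fits a DTM matched in
#' K and alpha, and scores recovery as the matched slice-averaged mean
#' cosine similarity between true and fitted topic-word distributions.
#'
#' @param spec A [dtm_sim_spec()] describing the simulation.
#' @param config Optional [dtm_config()]; by default K, alpha and
#'   chain_var follow the simulation spec, with `fit_seed` seeding the
#'   initialization.
#' @param fit_seed Seed for the fit (initialization only).
#' @return List with `mean_cosine`, `match`, `fit`, `truth`, `corpus`.
#' @export
run_topic_recovery <- function(spec = dtm_sim_spec(), config = NULL,
                               fit_seed = 1) {
  sim <- generate_dtm_corpus(spec)
  if (is.null(config))
    config <- dtm_config(n_topics = spec$n_topics, alpha = spec$alpha,
                         chain_var = spec$chain_var, seed = fit_seed)
  fit <- fit_dtm(sim$corpus, config)
  match <- match_topics(sim$truth$pi, fit$topic_word)
  list(mean_cosine = match$mean_cosine, match = match, fit = fit,
       truth = sim$truth, corpus = sim$corpus)
}

#' End-to-end mode-of-action recovery benchmark
#'
#' Simulates a repeated-dose study with planted MoA modules, runs the full
#' pipeline (fold changes, DEG selection, corpus encoding, DTM fit, hard
#' topic assignment) and scores how well the assigned topics recover the
#' planted groups with the adjusted Rand index over documents.
#'
#' @param spec A [study_sim_spec()].
#' @param n_topics Topics to fit; defaults to the number of planted groups.
#' @param deg_threshold Log2 fold-change DEG cutoff.
#' @param fit_seed Seed for the fit.
#' @param config Optional [dtm_config()] overriding the defaults.
#' @return List with `ari`, `assignments`, `fit`, `corpus`, `truth`.
#' @export
run_moa_recovery <- function(spec = study_sim_spec(), n_topics = spec$n_groups,
                             deg_threshold = 1, fit_seed = 1, config = NULL) {
  sim <- generate_expression_study(spec)
  corpus <- build_corpus(sim$study, deg_threshold = deg_threshold)
  if (is.null(config))
    config <- dtm_config(n_topics = n_topics, seed = fit_seed)
  fit <- fit_dtm(corpus, config)
  assignments <- assign_topics(fit)
  true_group <- unname(sim$truth$moa[assignments$compound_id])
  ari <- mclust::adjustedRandIndex(assignments$assigned_topic, true_group)
  list(ari = ari, assignments = assignments, fit = fit, corpus = corpus,
       truth = sim$truth)
}
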