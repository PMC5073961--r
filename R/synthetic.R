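#' Specification of a simulated DTM corpus
#'
#' Defaults describe the standard topic-recovery benchmark: a small,
#' well-separated corpus drawn exactly from the model's generative process.
#'
#' @param n_topics,n_words,n_slices Corpus dimensions (`n_words` must be
#'   even: the vocabulary is direction-split, two words per synthetic gene).
#' @param docs_per_slice Documents per time slice.
#' @param tokens_mean,tokens_dispersion Negative-binomial document-length
#'   model (mean and size); real DEG lists vary in size, so lengths do too.
#' @param alpha Dirichlet concentration of the document-topic mixtures.
#' @param chain_var Per-slice random-walk variance of the topic chains.
#' @param init_var Variance of the slice-1 natural parameters around 0;
#'   the default `1000 * chain_var` gives well-separated (realistically
#'   sparse) topics.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `dtm_sim_spec`.
#' @export
dtm_sim_spec <- function(n_topics = 3, n_words = 200, n_slices = 4,
                         docs_per_slice = 120, tokens_mean = 150,
                         tokens_dispersion = 10, alpha = 0.05,
                         chain_var = 0.005, init_var = 1000 * chain_var,
                         seed = 7) {
  spec <- list(n_topics = as.integer(n_topics), n_words = as.integer(n_words),
               n_slices = as.integer(n_slices),
               docs_per_slice = as.integer(docs_per_slice),
               tokens_mean = tokens_mean, tokens_dispersion = tokens_dispersion,
               alpha = alpha, chain_var = chain_var, init_var = init_var,
               seed = as.integer(seed))
  with(spec, {
    if (n_topics < 1 || n_words < 2 || n_slices < 1 || docs_per_slice < 1)
      .stopf("all dimensions must be positive")
    if (n_words %% 2L != 0L) .stopf("n_words must be even (direction-split vocabulary)")
    if (alpha <= 0 || chain_var <= 0 || init_var <= 0 ||
        tokens_mean <= 0 || tokens_dispersion <= 0)
      .stopf("all continuous parameters must be positive")
  })
  structure(spec, class = "dtm_sim_spec")
}

#' Forward-sample a corpus from the DTM generative process
#'
#' Draws per-topic natural-parameter chains
#' (`beta_1 ~ N(0, init_var)`, `beta_t ~ N(beta_{t-1}, chain_var)`),
#' softmax-transforms them into per-slice topic-word distributions, draws a
#' Dirichlet topic mixture per document and samples its tokens from the
#' mixture of multinomials.
#'
#' @param spec A [dtm_sim_spec()].
#' @return List with `corpus` (a `dtm_corpus`) and `truth`: `pi` (list over
#'   slices of K x W true topic-word distributions), `beta` (list over
#'   topics of T x W chains), `theta` (documents x K mixtures).
#' @export
generate_dtm_corpus <- function(spec = dtm_sim_spec()) {
  stopifnot(inherits(spec, "dtm_sim_spec"))
  set.seed(spec$seed)
  K <- spec$n_topics; W <- spec$n_words; T_ <- spec$n_slices
  gene_ids <- sprintf("g%04d", seq_len(W %/% 2L))
  vocab <- build_vocabulary(gene_ids)

  beta <- lapply(seq_len(K), function(k) {
    b <- matrix(0, T_, W)
    b[1, ] <- stats::rnorm(W, 0, sqrt(spec$init_var))
    if (T_ > 1L) for (t in 2:T_)
      b[t, ] <- b[t - 1, ] + stats::rnorm(W, 0, sqrt(spec$chain_var))
    b
  })
  pi_true <- lapply(seq_len(T_), function(t) {
    m <- do.call(rbind, lapply(beta, function(b) softmax_probs(b[t, ])))
    colnames(m) <- vocab$words
    m
  })

  n_docs <- T_ * spec$docs_per_slice
  theta <- .rdirichlet(n_docs, rep(spec$alpha, K))
  lengths_ <- pmax(1L, stats::rnbinom(n_docs, mu = spec$tokens_mean,
                                      size = spec$tokens_dispersion))
  documents <- vector("list", n_docs)
  i <- 0L
  for (t in seq_len(T_)) {
    for (j in seq_len(spec$docs_per_slice)) {
      i <- i + 1L
      zc <- stats::rmultinom(1, lengths_[i], theta[i, ])[, 1]
      counts <- numeric(W)
      for (k in which(zc > 0L))
        counts <- counts + stats::rmultinom(1, zc[k], pi_true[[t]][k, ])[, 1]
      ids <- unname(which(counts > 0L))
      documents[[i]] <- list(doc_id = sprintf("sim%04d_t%d", j, t),
                             compound_id = sprintf("sim%04d", j),
                             time_point = as.numeric(t),
                             slice_index = t - 1L,
                             word_ids = ids - 1L,
                             counts = as.integer(counts[ids]))
    }
  }
  list(corpus = .new_corpus(vocab, documents, as.numeric(seq_len(T_))),
       truth = list(pi = pi_true, beta = beta, theta = theta,
                    doc_lengths = as.integer(lengths_), spec = spec))
}

#' Specification of a simulated repeated-dose expression study
#'
#' Emulates a two-dose-group (control/treated), multi-replicate,
#' multi-time-point toxicogenomics design with planted mode-of-action
#' (MoA) gene modules: every compound belongs to one MoA group, and all
#' compounds of a group perturb the same gene module with the same log2
#' effect, modulated over time by the group's response profile. Defaults
#' describe the standard end-to-end recovery benchmark.
#'
#' @param n_compounds Number of compounds (split evenly across groups).
#' @param n_groups Number of MoA groups.
#' @param module_size Genes per group module (modules are disjoint).
#' @param effect_size Log2 effect added to module genes in treated samples.
#' @param time_profiles Character vector (length `n_groups`, recycled) of
#'   per-group response profiles: `"sustained"`, `"transient"`,
#'   `"delayed"`, or `"progressive"`. The default is sustained for every
#'   group, so cluster recovery measures topic separation rather than DEG
#'   detectability; the time-varying profiles drive the word-evolution
#'   analyses.
#' @param time_points Time-point labels (default the 4/8/15/29-day
#'   repeated-dose schedule).
#' @param replicates Replicates per (compound, time, dose) cell.
#' @param noise_sd Log2-scale measurement noise standard deviation.
#' @param n_genes Size of the gene universe.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 intensity
#'   distribution.
#' @param seed Integer seed.
#' @return An object of class `study_sim_spec`.
#' @export
study_sim_spec <- function(n_compounds = 24, n_groups = 4, module_size = 40,
                           effect_size = 2.0,
                           time_profiles = "sustained",
                           time_points = c(4, 8, 15, 29), replicates = 3,
                           noise_sd = 0.4, n_genes = 1000,
                           baseline_mean = 8, baseline_sd = 1.5, seed = 11) {
  spec <- list(n_compounds = as.integer(n_compounds),
               n_groups = as.integer(n_groups),
               module_size = as.integer(module_size),
               effect_size = effect_size,
               time_profiles = rep_len(time_profiles, n_groups),
               time_points = as.numeric(time_points),
               replicates = as.integer(replicates),
               noise_sd = noise_sd, n_genes = as.integer(n_genes),
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               seed = as.integer(seed))
  if (spec$n_compounds < spec$n_groups) .stopf("need at least one compound per group")
  if (spec$module_size * spec$n_groups > spec$n_genes)
    .stopf("disjoint modules need module_size * n_groups <= n_genes")
  if (spec$noise_sd < 0 || !is.finite(spec$effect_size))
    .stopf("invalid noise or effect size")
  bad <- setdiff(spec$time_profiles,
                 c("sustained", "transient", "delayed", "progressive"))
  if (length(bad)) .stopf("unknown time profile: %s", bad[1])
  structure(spec, class = "study_sim_spec")
}

# Per-slice effect multipliers of the named response profiles, defined on a
# 4-point template and linearly interpolated to other slice counts.
.profile_multipliers <- function(profile, n_slices) {
  template <- switch(profile,
    sustained   = c(1, 1, 1, 1),
    transient   = c(1, 0.5, 0.2, 0),
    delayed     = c(0, 0.3, 0.8, 1),
    progressive = c(0.25, 0.5, 0.75, 1))
  if (n_slices == 4L) return(template)
  stats::approx(seq(0, 1, length.out = 4), template,
                xout = seq(0, 1, length.out = n_slices))$y
}

#' Simulate a repeated-dose expression study with planted MoA modules
#'
#' Control samples are per-gene baselines plus log2 noise; treated samples
#' additionally carry the compound's group module effect scaled by the
#' group's time profile. The sample count is
#' `n_compounds * replicates * length(time_points) * 2` (two dose groups).
#'
#' @param spec A [study_sim_spec()].
#' @return List with `study` (an [expression_study()]) and `truth`:
#'   `moa` (named group index per compound), `modules` (gene ids per
#'   group), `profiles`, `multipliers` (group x slice effect multipliers).
#' @export
generate_expression_study <- function(spec = study_sim_spec()) {
  stopifnot(inherits(spec, "study_sim_spec"))
  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  compounds <- sprintf("cpd%03d", seq_len(spec$n_compounds))
  group_of <- stats::setNames(rep_len(seq_len(spec$n_groups), spec$n_compounds),
                              compounds)
  modules <- lapply(seq_len(spec$n_groups), function(g)
    genes[((g - 1L) * spec$module_size + 1L):(g * spec$module_size)])
  T_ <- length(spec$time_points)
  mult <- do.call(rbind, lapply(spec$time_profiles, .profile_multipliers,
                                n_slices = T_))

  meta <- expand.grid(replicate = seq_len(spec$replicates),
                      dose_group = c("control", "treated"),
                      time_point = spec$time_points,
                      compound_id = compounds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("compound_id", "time_point", "dose_group", "replicate")]
  meta$sample_id <- sprintf("%s_%gd_%s_r%d", meta$compound_id, meta$time_point,
                            substr(meta$dose_group, 1, 3), meta$replicate)
  n_samples <- nrow(meta)

  baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
  values <- matrix(stats::rnorm(spec$n_genes * n_samples, 0, spec$noise_sd),
                   spec$n_genes, n_samples) + baseline
  slice_of <- match(meta$time_point, sort(unique(spec$time_points)))
  treated <- meta$dose_group == "treated"
  for (j in which(treated)) {
    g <- group_of[[meta$compound_id[j]]]
    values[match(modules[[g]], genes), j] <-
      values[match(modules[[g]], genes), j] +
      spec$effect_size * mult[g, slice_of[j]]
  }
  colnames(values) <- meta$sample_id
  study <- expression_study(values, meta[, c("sample_id", "compound_id",
                                             "time_point", "dose_group",
                                             "replicate")], genes)
  list(study = study,
       truth = list(moa = group_of, modules = modules,
                    profiles = spec$time_profiles, multipliers = mult,
                    spec = spec))
}

# Minimum-cost assignment (Hungarian algorithm, shortest augmenting paths,
# O(n^3)); returns for each row the assigned column.
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)            # p[j]: row matched to column j-1 (index 1 = virtual)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n) + 1L) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

#' Match recovered topics to ground truth
#'
#' Computes the slice-averaged cosine similarity between every (true,
#' recovered) topic pair and finds the one-to-one matching maximizing the
#' total similarity -- exhaustively over permutations for K <= 8, by the
#' Hungarian algorithm otherwise.
#'
#' @param true_pi,fitted_pi Lists over slices of K x W topic-word matrices
#'   (a single matrix is treated as one slice).
#' @return List with `matching` (for each true topic, the index of its
#'   recovered counterpart), `pair_cosines`, `mean_cosine`, and the full
#'   `similarity` matrix.
#' @export
match_topics <- function(true_pi, fitted_pi) {
  if (is.matrix(true_pi)) true_pi <- list(true_pi)
  if (is.matrix(fitted_pi)) fitted_pi <- list(fitted_pi)
  if (length(true_pi) != length(fitted_pi))
    .stopf("slice counts differ (%d vs %d)", length(true_pi), length(fitted_pi))
  K <- nrow(true_pi[[1]])
  if (nrow(fitted_pi[[1]]) != K || ncol(fitted_pi[[1]]) != ncol(true_pi[[1]]))
    .stopf("topic matrices must share K and W")
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim <- matrix(0, K, K)
  for (t in seq_along(true_pi))
    for (i in seq_len(K)) for (j in seq_len(K))
      sim[i, j] <- sim[i, j] + cosine(true_pi[[t]][i, ], fitted_pi[[t]][j, ])
  sim <- sim / length(true_pi)

  if (K <= 8L) {
    perms <- .permutations(K)
    scores <- apply(perms, 1, function(p) sum(sim[cbind(seq_len(K), p)]))
    matching <- unname(perms[which.max(scores), ])
  } else {
    matching <- .hungarian(-sim)
  }
  pair <- sim[cbind(seq_len(K), matching)]
  list(matching = matching, pair_cosines = pair, mean_cosine = mean(pair),
       similarity = sim)
}

# All permutations of 1..n as rows (n small).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1L))
  }))
}
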