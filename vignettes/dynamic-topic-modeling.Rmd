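---
title: "Dynamic topic modeling of time-course toxicogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic topic modeling of time-course toxicogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtmtox)
```

## The problem

Repeated-dose toxicogenomics studies profile livers (or other tissues) of
animals treated with many compounds, at several time points, against matched
vehicle controls. Two questions recur: which compounds perturb the same
biological programs (mode-of-action grouping), and how those programs evolve
over the treatment course. Classical clustering collapses the time axis or
treats time points as independent columns; `dtmtox` instead treats each
compound-by-time differential expression signature as a *document* and fits a
Dynamic Topic Model (DTM), in which topics — probability distributions over
direction-tagged gene "words" — drift smoothly across ordered time slices.

## From contrasts to a corpus

For every compound and time point with both dose groups present, replicates
are averaged in log2 space and the treated-minus-control difference `d_g` is
computed per gene. The reported fold change is linear and
direction-normalized, `2^|d_g|` (always at least 1), with the sign kept as a
direction label; a zero difference counts as "up", a deterministic
tie-break. Genes passing the DEG cutoff (default `|log2 FC| >= 1`, i.e.
two-fold; the cutoff is exposed because the field has no single convention)
become words:

* word identity: `<gene>_up` or `<gene>_down` — induction and repression of
  the same gene are different tokens, so a vocabulary over `G` genes has
  exactly `2G` words;
* word count: `round(100 * fold_change)`, half away from zero, floored at 1
  so every retained DEG contributes at least one token. The down-regulated
  direction uses the direction-normalized (control/treated) ratio, so
  repression is weighted symmetrically with induction rather than being
  crushed into counts below 100.

Documents are grouped slice-major into an LDA-C corpus with a slice-count
sidecar, a vocabulary file and a document-metadata table. A compound missing
any contrast is dropped entirely by default (keeping every slice populated by
the same compounds), with `keep_partial = TRUE` to override. Conditions whose
DEG list is empty yield empty documents and are reported; their posterior is
simply the prior.

## The model

With `K` topics, `T` slices and `W` words, each topic `k` carries natural
parameters `beta_{t,k,w}` chained by a Gaussian random walk:

* `beta_1 ~ N(0, (init_var + chain_var) I)`,
  `beta_t | beta_{t-1} ~ N(beta_{t-1}, chain_var I)`;
* word distribution `pi_{t,k} = softmax(beta_{t,k,.})`;
* document `d` in slice `t`: topic mixture `theta_d ~ Dirichlet(alpha)`,
  token topics `z ~ theta_d`, tokens `w ~ pi_{t,z}`.

The posterior is intractable (Gaussian–multinomial non-conjugacy), so
inference is variational EM:

* **E-step.** Per document, the standard mean-field fixed point:
  responsibilities `phi[n,k] ∝ exp(digamma(gamma_k) + E[log pi_{t,k,w_n}])`
  and `gamma_k = alpha + sum_n c_n phi[n,k]`, iterated to `doc_tol` on the
  mean absolute change in `gamma`. The identity
  `sum(gamma) = K*alpha + N_d` holds after every update.
* **M-step.** Per topic, the expected counts per (slice, word) are the
  "data" for the chain. Variational observations `beta_hat_{t,w}` with fixed
  variance `obs_var` are smoothed by a Kalman forward filter and
  Rauch–Tung–Striebel backward smoother into marginal means `m_tilde` and
  variances `V_tilde`; the intractable softmax normalizer is bounded through
  the auxiliary variable `zeta_t = sum_w exp(m_tilde + V_tilde/2)`. Because
  `obs_var` is fixed, the smoother is a *linear* map `m_tilde = S beta_hat`
  with word-independent variances, and the per-topic bound is smooth and
  concave in `beta_hat`; it is maximized by gradient ascent with a
  backtracking line search (at most `chain_max_iter` steps), which
  guarantees the bound never decreases.

Initialization pools all slices into a static LDA (variational EM with
point-estimated topics, seeded random start) and replicates the log of each
floored, renormalized topic across slices. Like any topic model, the
objective is multimodal: a small fraction of random starts merge or split
clusters at a clearly worse bound, so the initializer runs `init_starts`
(default 4) restarts with seeds derived from the main seed and keeps the
best static bound. The only randomness in the whole fit is this
initialization, so a fit is bit-reproducible from its seed.

### Two details worth knowing

**Best-of-two E-step.** A warm start from the previous iteration's `gamma`
makes the EM a strict coordinate ascent, but with sparse priors (small
`alpha`) it can freeze early topic commitments at a poor stationary point. A
cold restart escapes such points but can, in rare iterations, land slightly
below the previous bound. The E-step therefore runs both and keeps the
higher bound: monotone by construction, and free of the commitment trap.

**What the reported ELBO is.** The chain contribution drops cross-slice
posterior covariances (as the reference DTM bound does) and the softmax is
handled through the `zeta` bound, so the trace is a bound on a bound; it is
still a deterministic objective that every step ascends, which is what the
monotonicity tests assert (tolerance `1e-6` relative per iteration).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_topics` | 20 | topics; the scale used for a ~131-compound liver study |
| `alpha` | 0.01 | Dirichlet document prior; smaller = fewer topics per sample |
| `chain_var` | 0.005 | random-walk variance per slice; smaller = slices more alike |
| `init_var` | `1000 * chain_var` | slice-1 anchor around 0 (diffuse) |
| `obs_var` | 0.5 | variational observation variance, fixed (not optimized) |
| `init_starts` | 4 | LDA-initialization restarts, best static bound kept |
| `em_rel_tol` / `em_max_iter` | 1e-4 / 50 | outer EM stopping rule |
| `doc_tol` / `doc_max_iter` | 1e-3 / 100 | per-document inner loop |
| `deg_threshold` | 1 | log2 fold-change DEG cutoff (corpus building) |
| `top_n` | 300 | per-slice ranking depth for interpretation |

`init_var` deserves a note. The natural parameters live on a log-probability
scale where realistic topics span several units. A tight slice-1 prior
(e.g. `10 * chain_var` = 0.05 at the default `chain_var`) shrinks those
values toward 0 and visibly flattens every fitted topic toward uniformity;
fits stop agreeing with a static LDA even on a single-slice corpus. The
default therefore follows the diffuse-anchor convention of the reference DTM
implementation (`1000 * chain_var`), which makes the first slice essentially
data-driven while `chain_var` alone controls slice-to-slice coupling.
Reducing `chain_var` tenfold measurably reduces the mean total-variation
distance between consecutive-slice word distributions — the parameter's
documented semantics — and this is asserted in the acceptance suite.

## Interpretation outputs

* `assign_topics()` — each document goes to its argmax P(T|D) (ties to the
  lowest index, logged); the compound-time conditions sharing a topic form a
  sample cluster.
* `rank_genes()` / `top_n()` — words ordered by P(W|T) at one slice
  (ties by word id), truncated at `n` (default 300).
* `representative_genes()` — words ranked within the top `n` at *every*
  slice (the intersection reading of "within 300 at all time points"; the
  union variant can be had via `topic_membership_counts(per_slice = TRUE)`).
* `topic_membership_counts()` — for each word, the number of topics whose
  top-`n` (any slice, by default) contains it; the per-slice variant is a
  configuration flag because published figures have used both readings.
* `fisher_enrichment()` / `enrich_topics()` — directions are stripped and
  duplicates collapsed (gene-set collections are gene-keyed, so `Gene_up`
  and `Gene_down` must not double-count), then each set is tested by the
  one-sided hypergeometric tail `P(X >= a)` against the corpus gene universe
  by default, with Benjamini–Hochberg adjustment within each (topic, slice)
  query.

## Synthetic data: what it does and does not emulate

Two seed-deterministic generators make the whole pipeline testable with no
external download.

`generate_dtm_corpus()` samples exactly from the generative process above,
with negative-binomial document lengths (real DEG lists vary in size). Its
defaults — K = 3, W = 200, T = 4, 120 documents per slice, ~150 tokens per
document, `alpha` 0.05, `chain_var` 0.005, seed 7 — are the package's
standard topic-recovery benchmark: `run_topic_recovery()` fits a matched
model and scores the optimal one-to-one topic matching (exhaustive for
K <= 8, Hungarian algorithm otherwise) by slice-averaged cosine similarity.

`generate_expression_study()` emulates a two-dose repeated-dose design:
per-gene baselines, i.i.d. log2 noise, and disjoint planted gene modules
shared by all compounds of a mode-of-action group, scaled over time by a
response profile (`sustained`, `transient`, `delayed`, `progressive` —
per-slice multipliers `[1,1,1,1]`, `[1,.5,.2,0]`, `[0,.3,.8,1]`,
`[.25,.5,.75,1]`). The default benchmark plants 4 groups of 6 compounds
(module 40 genes, +2 log2, noise 0.4, 3 replicates, seed 11) and
`run_moa_recovery()` scores document assignments against the planted groups
with the adjusted Rand index. The default profile is *sustained for every
group*: the benchmark is meant to measure whether topics separate the
groups, and a profile that drives the effect below the DEG threshold at some
slices would instead measure detectability (near-empty documents cannot
carry any signature). The time-varying profiles are exercised by their own
tests of per-slice fold-change structure.

What the simulators do **not** emulate: probe-level artifacts, batch
effects, correlated noise between genes, dose-response beyond two groups,
overlapping or partially penetrant modules, and compound-specific effect
heterogeneity. Passing recovery benchmarks therefore shows the inference
machinery is sound, not that real TG-GATEs-scale data would cluster as
cleanly.

## Numerical choices

* All probability math is in log space with log-sum-exp; probabilities are
  floored at `1e-12` before any log, so no natural parameter is ever
  infinite.
* Rounding of word counts is half away from zero (base R's `round()` is
  half-to-even, which would make `count(1.005)` depend on parity).
* Ties: zero log2 difference is "up"; equal P(T|D) goes to the lowest topic
  index; equal P(W|T) ranks by ascending word id. Every output is
  deterministic.
* The single-slice reduction check scores both the DTM's implied topics and
  a converged static LDA's topics on the *same* static variational bound
  (`lda_bound()` with topics held fixed). The DTM's own ELBO additionally
  carries Gaussian prior/entropy terms and a variance-inflated normalizer
  (`+V_tilde/2` per word inside `zeta`) that have no LDA counterpart; since
  the smoothed variances are word-uniform these terms shift the bound
  without changing any fitted distribution, so the common-objective
  comparison is the meaningful one.
* Benchmark problem sizes (480-document recovery corpus, 96-document MoA
  study, 20 fuzzed corpora for monotonicity, 200 chains against the dense
  Gaussian oracle, 500 fuzzed enrichment tables) were chosen so the full
  suite re-runs in a few minutes on one core while keeping every check at a
  scale where failure modes are visible.

## Known limitations

* `alpha`, `chain_var` and `obs_var` are fixed, not learned; there is no
  held-out-likelihood model selection for K.
* The document-topic prior is a symmetric Dirichlet, as in the released DTM
  software; a logistic-normal document prior is not implemented.
* The chain ELBO ignores cross-slice posterior covariances (standard for
  this model family), so reported ELBO values are comparable within a fit,
  not across models.
* Enrichment treats gene sets as flat lists: no ontology-graph
  propagation, no versioned KEGG/GO retrieval.

## A minimal run

```{r example, eval = FALSE}
sim <- generate_expression_study(study_sim_spec(n_compounds = 8, n_groups = 2,
                                                n_genes = 300, seed = 11))
corpus <- build_corpus(sim$study, deg_threshold = 1)
fit <- fit_dtm(corpus, dtm_config(n_topics = 2, seed = 1))
assign_topics(fit)
head(rank_genes(fit, topic = 1, slice = 1))
```
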