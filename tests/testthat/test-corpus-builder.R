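test_that("fold changes follow the direction-normalized 2^|mean difference| rule", {
  shifts <- matrix(c(0, 2, -1.5), ncol = 1,
                   dimnames = list(NULL, "cpdA@4"))
  study <- make_exact_study(shifts)
  fc <- compute_fold_changes(study, "cpdA", 4)
  # zero difference: fold 1, tie resolved as "up"
  expect_equal(fc$fold_change[1], 1.0)
  expect_equal(fc$direction[1], "up")
  # +2 in log2: linear fold 4, up
  expect_equal(fc$fold_change[2], 4.0)
  expect_equal(fc$direction[2], "up")
  # -1.5 in log2: direction-normalized fold 2^1.5, down
  expect_equal(fc$fold_change[3], 2^1.5)
  expect_equal(fc$direction[3], "down")
})

test_that("fold changes agree with a naive per-gene loop oracle", {
  study <- make_random_study(seed = 7)
  fc <- compute_fold_changes(study, "c1", 8)
  meta <- study$sample_meta
  for (i in seq_along(study$gene_ids)) {
    trt <- study$values[i, meta$compound_id == "c1" & meta$time_point == 8 &
                             meta$dose_group == "treated"]
    ctl <- study$values[i, meta$compound_id == "c1" & meta$time_point == 8 &
                             meta$dose_group == "control"]
    d <- mean(trt) - mean(ctl)
    expect_equal(fc$fold_change[i], 2^abs(d), tolerance = 1e-12)
    expect_equal(fc$direction[i], if (d >= 0) "up" else "down")
  }
})

test_that("permuting replicates within a dose group leaves fold changes unchanged", {
  study <- make_random_study(seed = 8)
  fc1 <- compute_fold_changes(study, "c2", 4)
  meta <- study$sample_meta
  sel <- which(meta$compound_id == "c2" & meta$time_point == 4 &
                 meta$dose_group == "treated")
  perm <- seq_len(ncol(study$values))
  perm[sel] <- rev(sel)
  study2 <- expression_study(study$values[, perm], meta[perm, ], study$gene_ids)
  fc2 <- compute_fold_changes(study2, "c2", 4)
  expect_equal(fc1$fold_change, fc2$fold_change)
  expect_equal(fc1$direction, fc2$direction)
})

test_that("a missing dose group raises a contrast-unavailable error naming the cell", {
  study <- make_random_study(seed = 9)
  keep <- !(study$sample_meta$compound_id == "c1" &
              study$sample_meta$time_point == 4 &
              study$sample_meta$dose_group == "treated")
  study2 <- expression_study(study$values[, keep], study$sample_meta[keep, ],
                             study$gene_ids)
  expect_error(compute_fold_changes(study2, "c1", 4), "c1.*4.*treated")
})

test_that("DEG selection applies the log2 cutoff and matches a brute-force filter", {
  recs <- data.frame(gene_id = c("a", "b", "c"),
                     fold_change = c(2.0, 1.9, 10),
                     stringsAsFactors = FALSE)
  out <- select_degs(recs, 1.0)
  expect_equal(out$is_deg, c(TRUE, FALSE, TRUE))     # 2.0 hits, 1.9 misses
  expect_true(all(select_degs(recs, 0)$is_deg))      # vacuous cutoff
  expect_error(select_degs(recs, -0.1), "non-negative")

  set.seed(13)
  rnd <- data.frame(gene_id = sprintf("g%d", 1:200),
                    fold_change = 2^runif(200, 0, 3))
  thr <- 0.8
  flagged <- select_degs(rnd, thr)$is_deg
  oracle <- vapply(seq_len(200), function(i)
    abs(log2(rnd$fold_change[i])) >= thr, logical(1))
  expect_identical(flagged, oracle)
})

test_that("vocabulary is direction-split, ordered and losslessly decodable", {
  v <- build_vocabulary("g1")
  expect_identical(v$words, c("g1_up", "g1_down"))
  expect_error(build_vocabulary(c("a", "b", "a")), "duplicate.*a")

  set.seed(5)
  ids <- sprintf("gene%03d", sample(1:500, 60))
  v <- build_vocabulary(ids)
  expect_length(v$words, 2L * length(ids))
  # round trip: word_id -> (gene, direction) -> word -> word_id
  dec <- decode_words(v, seq_along(v$words) - 1L)
  expect_identical(paste0(dec$gene_id, "_", dec$direction), v$words)
  expect_identical(unname(v$index[dec$word]), dec$word_id)
})

test_that("document encoding applies the 100x fold-change count rule", {
  v <- build_vocabulary(c("Acot1", "Stac3"))
  recs <- data.frame(gene_id = c("Acot1", "Stac3"),
                     compound_id = "WY", time_point = 4,
                     fold_change = c(2.5, 1.004),
                     direction = c("up", "down"),
                     is_deg = TRUE, stringsAsFactors = FALSE)
  corp <- encode_documents(recs, v)
  d <- corp$documents[[1]]
  expect_identical(corp$vocabulary$words[d$word_ids + 1L],
                   c("Acot1_up", "Stac3_down"))
  expect_identical(d$counts[match("Acot1_up", corp$vocabulary$words[d$word_ids + 1L])],
                   250L)                     # round(100 * 2.5)
  expect_identical(d$counts[match("Stac3_down", corp$vocabulary$words[d$word_ids + 1L])],
                   100L)                     # round(100.4)
  expect_true(all(d$counts >= 1L))
})

test_that("encoding rejects unknown genes and sub-unity fold changes", {
  v <- build_vocabulary("g1")
  base <- data.frame(gene_id = "g1", compound_id = "c", time_point = 4,
                     fold_change = 2, direction = "up", is_deg = TRUE,
                     stringsAsFactors = FALSE)
  bad_gene <- transform(base, gene_id = "gX")
  expect_error(encode_documents(bad_gene, v), "gX")
  bad_fc <- transform(base, fold_change = 0.5)
  expect_error(encode_documents(bad_fc, v), "invariant")
})

test_that("conditions with no DEGs yield empty documents and are reported", {
  v <- build_vocabulary(c("g1", "g2"))
  recs <- data.frame(gene_id = c("g1", "g2"),
                     compound_id = c("c1", "c2"), time_point = 4,
                     fold_change = c(4, 4), direction = "up",
                     is_deg = c(TRUE, FALSE), stringsAsFactors = FALSE)
  expect_message(corp <- encode_documents(recs, v), "c2")
  sizes <- vapply(corp$documents, function(d) length(d$word_ids), integer(1))
  expect_identical(sizes, c(1L, 0L))
})

test_that("corpus construction is deterministic and slice-major with full grids", {
  study <- make_random_study(n_compounds = 3, times = c(4, 8, 15), seed = 21)
  corp <- suppressMessages(build_corpus(study, deg_threshold = 0.5))
  expect_identical(length(corp$documents), 3L * 3L)    # compounds x times
  expect_identical(corp$slice_sizes, c(3L, 3L, 3L))
  expect_true(!is.unsorted(corp$doc_meta$slice_index))
  # byte-identical output for identical input
  d1 <- file.path(tempdir(), "corp1"); d2 <- file.path(tempdir(), "corp2")
  write_corpus(corp, d1)
  write_corpus(suppressMessages(build_corpus(study, deg_threshold = 0.5)), d2)
  for (f in c("corpus.ldac", "corpus-seq.dat", "corpus.vocab", "corpus-docs.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("compounds with incomplete time courses are dropped with a warning", {
  study <- make_random_study(n_compounds = 2, times = c(4, 8), seed = 22)
  keep <- !(study$sample_meta$compound_id == "c2" &
              study$sample_meta$time_point == 8)
  study2 <- expression_study(study$values[, keep], study$sample_meta[keep, ],
                             study$gene_ids)
  expect_warning(corp <- suppressMessages(build_corpus(study2, deg_threshold = 0.2)),
                 "c2")
  expect_true(all(corp$doc_meta$compound_id == "c1"))
})
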