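test_that("pairs with missing embeddings are removed and reported", {
  pairs <- make_toy_pairs(5L, 5L)
  ids <- unique(c(pairs$drug_id, pairs$disease_id))
  tab <- random_embedding_table(ids, 4L)
  res <- filter_missing(pairs, tab)
  expect_equal(res$kept, pairs)
  expect_length(res$removed_ids, 0L)

  tab2 <- tab[!(rownames(tab) %in% c("D01", "D03")), ]
  res2 <- filter_missing(pairs, tab2)
  expect_equal(nrow(res2$kept), 8L)
  expect_equal(res2$removed_ids, c("D01", "D03"))

  expect_warning(res3 <- filter_missing(pairs, tab[0, , drop = FALSE]),
                 "no pairs left")
  expect_equal(nrow(res3$kept), 0L)
})

test_that("pair features concatenate drug then disease embeddings", {
  tab <- rbind(DRG = c(1, 0), DIS = c(0, 2))
  pr <- data.frame(drug_id = "DRG", disease_id = "DIS", label = 1L)
  expect_equal(as.numeric(build_pair_features(tab, pr)), c(1, 0, 0, 2))
  # order sensitivity
  pr_rev <- data.frame(drug_id = "DIS", disease_id = "DRG", label = 1L)
  expect_false(isTRUE(all.equal(as.numeric(build_pair_features(tab, pr)),
                                as.numeric(build_pair_features(tab, pr_rev)))))
  tab100 <- random_embedding_table(c("a", "b"), 100L)
  expect_equal(ncol(build_pair_features(
    tab100, data.frame(drug_id = "a", disease_id = "b", label = 1L))), 200L)
  expect_error(build_pair_features(tab, data.frame(drug_id = "zz",
                                                   disease_id = "DIS",
                                                   label = 1L)), "missing")
})

test_that("triple features concatenate drug1, drug2, then side effect", {
  tab <- rbind(A = c(1, 0), B = c(0, 1), SE = c(2, 2))
  tr <- data.frame(drug1 = "A", side_effect = "SE", drug2 = "B", label = 1L)
  expect_equal(as.numeric(build_triple_features(tab, tr)),
               c(1, 0, 0, 1, 2, 2))
  zero <- tab * 0
  expect_equal(as.numeric(build_triple_features(zero, tr)), rep(0, 6))
})

test_that("leave-one-out produces n singleton test folds", {
  labels <- rep(c(1L, -1L), c(43L, 50L))  # a 93-instance benchmark
  folds <- make_cv_splits(labels, "loo")
  expect_length(folds, 93L)
  expect_true(all(vapply(folds, function(f) length(f$test), 1L) == 1L))
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), 1:93)
})

test_that("stratified folds preserve class proportions and partition the data", {
  labels <- rep(c(1L, -1L), each = 10L)
  folds <- make_cv_splits(labels, "s5f", seed = 3L)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_equal(sum(labels[f$test] == 1L), 2L)
    expect_equal(sum(labels[f$test] == -1L), 2L)
    expect_length(intersect(f$train, f$test), 0L)
  }
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(tests), seq_along(labels))  # exact partition
  # near-proportionality with uneven classes
  lab2 <- rep(c(1L, -1L), c(43L, 50L))
  for (f in make_cv_splits(lab2, "s5f", seed = 1L)) {
    expect_lte(abs(sum(lab2[f$test] == 1L) - 43 / 5), 1)
    expect_lte(abs(sum(lab2[f$test] == -1L) - 50 / 5), 1)
  }
  expect_error(make_cv_splits(rep(c(1L, -1L), c(4L, 20L)), "s5f"),
               "at least 5")
})

test_that("cross-dataset folds train on one set and test the other's folds", {
  train_lab <- rep(c(1L, -1L), each = 10L)
  test_lab <- rep(c(1L, -1L), each = 15L)
  folds <- make_cv_splits(train_lab, "cross_dataset", seed = 2L,
                          test_labels = test_lab)
  expect_length(folds, 5L)
  for (f in folds) expect_equal(f$train, 1:20)
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), 1:30)
})

test_that("metrics match brute-force oracles on the toy ranking", {
  y <- c(1, 0, 1, 0)
  sc <- c(0.9, 0.8, 0.7, 0.1)
  m <- compute_metrics(y, sc, threshold = 0.5)
  expect_equal(m$auc, 0.75)
  expect_equal(m$auc, brute_force_auc(y, sc))
  # threshold 0.5 -> predictions (1,1,1,0): precision 2/3, recall 1
  expect_equal(m$f1, 0.8)
  # perfect ranking
  mp <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(mp$auc, 1)
  expect_equal(mp$auprc, 1)
  expect_equal(mp$ap50, 1)
  # score reversal flips AUC
  expect_equal(compute_metrics(y, -sc)$auc, 1 - m$auc)
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.3)), "single class")
})

test_that("rank-statistic AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    for (i in 1:10) {
      y <- rbinom(40, 1, 0.4)
      if (length(unique(y)) < 2) next
      sc <- rnorm(40) + y
      ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                            direction = "<")))
      expect_equal(compute_metrics(y, sc)$auc, ref, tolerance = 1e-12)
    }
  })
})

test_that("classifiers achieve perfect scores on separable data", {
  withr::with_seed(13, {
    n <- 20L
    y <- rep(c(1L, -1L), each = n / 2)
    x <- cbind(ifelse(y > 0, 1, -1) + rnorm(n, sd = 0.05), rnorm(n))
    folds <- make_cv_splits(y, "s5f", seed = 1L)
    for (fam in c("lr", "knn", "rf")) {
      rep_ <- train_eval(x, y, classifier_spec(fam), folds, seed = 1L)
      expect_equal(rep_$mean_f1, 1)
      expect_equal(rep_$mean_auc, 1)
    }
  })
})

test_that("label permutation drives AUC to chance", {
  aucs <- withr::with_seed(17, {
    n <- 40L
    x <- matrix(rnorm(n * 4), n)
    vapply(1:20, function(i) {
      y <- sample(rep(c(1L, -1L), each = n / 2))
      folds <- make_cv_splits(y, "s5f", seed = i)
      train_eval(x, y, classifier_spec("knn"), folds, seed = i)$mean_auc
    }, numeric(1))
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("evaluation is deterministic given the seed", {
  withr::with_seed(19, {
    n <- 30L
    y <- rep(c(1L, -1L), each = n / 2)
    x <- matrix(rnorm(n * 6), n) + as.numeric(y > 0)
    folds <- make_cv_splits(y, "s5f", seed = 4L)
    r1 <- train_eval(x, y, classifier_spec("rf"), folds, seed = 7L)
    r2 <- train_eval(x, y, classifier_spec("rf"), folds, seed = 7L)
    expect_identical(r1$scores, r2$scores)
  })
  # single-class training folds are refused with the fold named
  bad_folds <- list(list(train = 1:15, test = 16:30))
  y_bad <- rep(c(1L, -1L), each = 15L)
  x_bad <- matrix(rnorm(60), 30)
  expect_error(train_eval(x_bad, y_bad, classifier_spec("lr"), bad_folds),
               "fold 1")
})

test_that("negative triples avoid the known set and collisions", {
  known <- data.frame(drug1 = "DA", side_effect = "S1", drug2 = "DB",
                      label = 1L)
  # candidate space: 3 drugs x 1 SE = 3 unordered pairs; 2 free
  neg <- sample_negative_triples(known, 2L, c("DA", "DB", "DC"), "S1",
                                 seed = 1L)
  expect_equal(nrow(neg), 2L)
  expect_true(all(neg$label == 0L))
  expect_true(all(neg$drug1 < neg$drug2))
  keys <- paste(neg$drug1, neg$side_effect, neg$drug2)
  expect_false("DA S1 DB" %in% keys)
  expect_equal(anyDuplicated(keys), 0L)
  # forced: only one candidate remains
  known2 <- rbind(known, data.frame(drug1 = "DA", side_effect = "S1",
                                    drug2 = "DC", label = 1L))
  one <- sample_negative_triples(known2, 1L, c("DA", "DB", "DC"), "S1")
  expect_equal(paste(one$drug1, one$side_effect, one$drug2), "DB S1 DC")
  expect_error(sample_negative_triples(known2, 2L, c("DA", "DB", "DC"), "S1"),
               "only 1")
  # larger space: exhaustive disjointness
  drugs <- sprintf("D%02d", 1:12)
  ses <- sprintf("S%d", 1:4)
  known3 <- data.frame(drug1 = "D01", side_effect = "S1", drug2 = "D02",
                       label = 1L)
  big <- sample_negative_triples(known3, 200L, drugs, ses, seed = 9L)
  expect_equal(nrow(big), 200L)
  expect_equal(anyDuplicated(paste(big$drug1, big$side_effect, big$drug2)), 0L)
  expect_false(any(paste(big$drug1, big$side_effect, big$drug2) ==
                     "D01 S1 D02"))
})

test_that("occurrence scores count triples sharing the drug pair", {
  tr <- data.frame(drug1 = c("A", "A", "B", "A"),
                   side_effect = c("S1", "S2", "S1", "S3"),
                   drug2 = c("B", "B", "C", "B"), label = 1L)
  expect_equal(compute_occurrence_scores(tr), c(3L, 3L, 1L, 3L))
  # permutation invariance over input order
  perm <- c(3, 1, 4, 2)
  expect_equal(compute_occurrence_scores(tr[perm, ]),
               compute_occurrence_scores(tr)[perm])
  # unordered drug pairs: (B, A) counts with (A, B)
  tr2 <- tr; tr2$drug1[1] <- "B"; tr2$drug2[1] <- "A"
  expect_equal(compute_occurrence_scores(tr2), c(3L, 3L, 1L, 3L))
  rec <- triples_to_records(tr)
  expect_equal(rec$cooccurrence, c(3L, 3L, 1L, 3L))
  expect_true(all(rec$subject_score == 1 & rec$object_score == 1))
})

test_that("per-side-effect metrics average over side effects", {
  tr <- data.frame(drug1 = rep("A", 8), drug2 = rep("B", 8),
                   side_effect = rep(c("S1", "S2"), each = 4L),
                   label = rep(c(1L, 1L, 0L, 0L), 2L))
  sc <- c(0.9, 0.8, 0.2, 0.1,   # perfect for S1
          0.1, 0.2, 0.8, 0.9)   # inverted for S2
  m <- per_side_effect_metrics(tr, sc)
  expect_equal(nrow(m$per_side_effect), 2L)
  expect_equal(sort(m$per_side_effect$auc), c(0, 1))
  expect_equal(m$mean_auc, 0.5)
})

test_that("benchmark pair and triple files round-trip", {
  pf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("DRUG_ID,DISEASE_ID,LABEL", "d1,x1,1", "d2,x1,-1"), pf)
  pr <- read_labeled_pairs(pf)
  expect_equal(pr$label, c(1L, -1L))
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("DRUG1,SIDE_EFFECT,DRUG2,LABEL", "db,s1,da,1", "da,s2,dc,0"),
             tf)
  tr <- read_labeled_triples(tf)
  expect_equal(tr$drug1[1], "da")  # canonical ordering applied
  expect_equal(tr$drug2[1], "db")
})
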