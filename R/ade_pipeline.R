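#' Read a labelled drug--disease pair file
#'
#' CSV with columns `DRUG_ID`, `DISEASE_ID`, `LABEL` (+1 for a true
#' drug--ADE pair, -1 otherwise).
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `drug_id`, `disease_id`, `label`.
#' @export
read_labeled_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  stopifnot(all(c("drug_id", "disease_id", "label") %in% names(df)))
  df$label <- as.integer(df$label)
  if (!all(df$label %in% c(-1L, 1L))) stop("pair labels must be +1 or -1")
  if (anyDuplicated(df[c("drug_id", "disease_id")])) {
    stop("duplicate (drug, disease) pair")
  }
  df[c("drug_id", "disease_id", "label")]
}

#' Read a labelled polypharmacy triple file
#'
#' CSV with columns `DRUG1`, `SIDE_EFFECT`, `DRUG2`, `LABEL` (1 = the drug
#' pair causes the side effect, 0 = it does not). Drug pairs are unordered;
#' they are canonicalized lexicographically on read.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `drug1`, `side_effect`, `drug2`, `label`.
#' @export
read_labeled_triples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  stopifnot(all(c("drug1", "side_effect", "drug2", "label") %in% names(df)))
  df$label <- as.integer(df$label)
  if (!all(df$label %in% c(0L, 1L))) stop("triple labels must be 0 or 1")
  canonicalize_triples(df[c("drug1", "side_effect", "drug2", "label")])
}

canonicalize_triples <- function(triples) {
  swap <- triples$drug1 > triples$drug2
  tmp <- triples$drug1[swap]
  triples$drug1[swap] <- triples$drug2[swap]
  triples$drug2[swap] <- tmp
  triples
}

#' Drop pairs whose concepts lack embeddings
#'
#' Mirrors the benchmark preprocessing step in which drugs without an
#' embedding are removed before classification.
#'
#' @param pairs Labelled pair data frame.
#' @param table Embedding matrix with identifier rownames.
#' @return List with `kept` (pairs whose drug and disease both have
#'   vectors) and `removed_ids` (sorted unique missing concept ids).
#' @export
filter_missing <- function(pairs, table) {
  have <- rownames(table)
  miss_drug <- !(pairs$drug_id %in% have)
  miss_dis <- !(pairs$disease_id %in% have)
  removed <- sort(unique(c(pairs$drug_id[miss_drug],
                           pairs$disease_id[miss_dis])))
  kept <- pairs[!(miss_drug | miss_dis), , drop = FALSE]
  rownames(kept) <- NULL
  if (!nrow(kept)) warning("no pairs left after removing missing concepts")
  list(kept = kept, removed_ids = removed)
}

#' Pair features: concatenated drug and disease embeddings
#'
#' @param table Embedding matrix with identifier rownames.
#' @param pairs Labelled pair data frame (every concept must be present;
#'   see [filter_missing()]).
#' @return Numeric matrix, one row per pair, `2 * dim` columns.
#' @export
build_pair_features <- function(table, pairs) {
  miss <- setdiff(unique(c(pairs$drug_id, pairs$disease_id)),
                  rownames(table))
  if (length(miss)) {
    stop("missing embeddings (run filter_missing first): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  cbind(table[pairs$drug_id, , drop = FALSE],
        table[pairs$disease_id, , drop = FALSE])
}

#' Triple features: drug1, drug2, and side-effect embeddings concatenated
#'
#' With dimension-100 embeddings this yields a 300-component feature; with
#' dimension 256, a 768-component feature.
#'
#' @param table Embedding matrix with identifier rownames.
#' @param triples Labelled triple data frame.
#' @return Numeric matrix, one row per triple, `3 * dim` columns.
#' @export
build_triple_features <- function(table, triples) {
  ids <- unique(c(triples$drug1, triples$drug2, triples$side_effect))
  miss <- setdiff(ids, rownames(table))
  if (length(miss)) {
    stop("missing embeddings for: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  cbind(table[triples$drug1, , drop = FALSE],
        table[triples$drug2, , drop = FALSE],
        table[triples$side_effect, , drop = FALSE])
}

#' Cross-validation folds
#'
#' * `loo`: leave-one-out, `n` folds with a single test instance each.
#' * `s5f`: stratified 5-fold; within each class, members are shuffled and
#'   dealt round-robin so per-fold class counts are within one of exact
#'   proportionality.
#' * `cross_dataset`: train on the full first dataset, evaluate on each of
#'   the second dataset's 5 stratified folds (pass the second dataset's
#'   labels as `test_labels`), so cross-dataset numbers are comparable with
#'   the second dataset's own 5-fold numbers.
#'
#' @param labels Vector of class labels.
#' @param scheme `"loo"`, `"s5f"`, or `"cross_dataset"`.
#' @param seed Integer seed for the stratified shuffles.
#' @param n_folds Number of stratified folds (default 5).
#' @param test_labels Labels of the held-out dataset (cross_dataset only).
#' @return List of folds, each a list with integer `train` and `test`
#'   index vectors. For `cross_dataset`, `train` indexes `labels` and
#'   `test` indexes `test_labels`.
#' @export
make_cv_splits <- function(labels, scheme = c("loo", "s5f", "cross_dataset"),
                           seed = 1L, n_folds = 5L, test_labels = NULL) {
  scheme <- match.arg(scheme)
  n <- length(labels)
  if (n < 2L && scheme != "cross_dataset") stop("need at least two instances")
  if (scheme == "loo") {
    return(lapply(seq_len(n), function(i)
      list(train = setdiff(seq_len(n), i), test = i)))
  }
  stratified <- function(lab, k) {
    assignment <- integer(length(lab))
    for (cl in unique(lab)) {
      idx <- which(lab == cl)
      if (length(idx) < k) {
        stop("class ", cl, " has ", length(idx),
             " members; need at least ", k, " for stratified ", k, "-fold")
      }
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(f)
      list(train = which(assignment != f), test = which(assignment == f)))
  }
  if (scheme == "s5f") {
    return(with_seed(seed, stratified(labels, n_folds)))
  }
  if (is.null(test_labels)) {
    stop("cross_dataset scheme needs test_labels")
  }
  test_folds <- with_seed(seed, stratified(test_labels, n_folds))
  lapply(test_folds, function(f)
    list(train = seq_len(n), test = f$test))
}

#' Classifier specification
#'
#' The three classifier families used downstream, pinned to the named
#' settings so results do not drift with library defaults:
#' * `lr`: L1-penalized logistic regression (glmnet, `alpha = 1`,
#'   `lambda = 1/n`).
#' * `knn`: k-nearest neighbours, `k = 5`; the positive-class score is the
#'   fraction of positive votes among the neighbours.
#' * `rf`: random forest (ranger), `num_trees` trees, optional
#'   `max_depth`; the polypharmacy configuration is 100 trees with
#'   maximum depth 20.
#'
#' @param family `"lr"`, `"knn"`, or `"rf"`.
#' @param k Neighbour count for `knn`.
#' @param num_trees,max_depth Forest size and depth cap for `rf`
#'   (`max_depth = 0` means unlimited).
#' @param lambda Optional fixed penalty for `lr`; default `1/n` at fit
#'   time.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("lr", "knn", "rf"), k = 5L,
                            num_trees = 100L, max_depth = 0L,
                            lambda = NULL) {
  family <- match.arg(family)
  structure(list(family = family, k = as.integer(k),
                 num_trees = as.integer(num_trees),
                 max_depth = as.integer(max_depth), lambda = lambda),
            class = "classifier_spec")
}

# Fit on (x, y in {0,1}) and return a prediction closure giving
# positive-class probabilities.
fit_classifier <- function(spec, x, y, seed = 1L) {
  if (length(unique(y)) < 2L) {
    stop("single-class training fold; cannot fit a classifier")
  }
  switch(spec$family,
    lr = {
      lam <- if (is.null(spec$lambda)) 1 / length(y) else spec$lambda
      fit <- glmnet::glmnet(x, factor(y, levels = c(0, 1)),
                            family = "binomial", alpha = 1, lambda = lam,
                            standardize = TRUE)
      function(newx) as.numeric(predict(fit, newx = newx,
                                        type = "response")[, 1L])
    },
    knn = {
      function(newx) {
        pred <- class::knn(train = x, test = newx,
                           cl = factor(y, levels = c(0, 1)), k = spec$k,
                           prob = TRUE)
        p_win <- attr(pred, "prob")
        ifelse(pred == "1", p_win, 1 - p_win)
      }
    },
    rf = {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), x)
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = spec$num_trees,
                            max.depth = spec$max_depth, probability = TRUE,
                            seed = seed, num.threads = 1L)
      function(newx) {
        predict(fit, data = data.frame(newx),
                num.threads = 1L)$predictions[, "1"]
      }
    })
}

#' Binary classification metrics
#'
#' * F1 on the positive class at the given score threshold (0 when
#'   precision and recall are both undefined or zero).
#' * AUC via the rank statistic (Wilcoxon form, midranks for ties).
#' * AUPRC: average precision -- the sum of precision at each positive,
#'   weighted by the recall increment.
#' * AP@50: `sum_{i<=50} precision@i * rel(i) / min(50, n_positives)` over
#'   the top-50 ranked predictions.
#'
#' @param y_true 0/1 (or -1/+1) vector.
#' @param y_score Numeric scores, larger = more positive.
#' @param threshold Score threshold for the F1 point metric.
#' @return List with `f1`, `auc`, `auprc`, `ap50`.
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  y <- as.integer(y_true > 0)
  stopifnot(length(y) == length(y_score))
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("AUC undefined: y_true contains a single class")
  }
  r <- rank(y_score, ties.method = "average")
  auc <- (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)

  pred <- as.integer(y_score >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)

  ord <- order(y_score, decreasing = TRUE)
  ys <- y[ord]
  tp_cum <- cumsum(ys)
  prec <- tp_cum / seq_along(ys)
  rec_inc <- ys / npos
  auprc <- sum(prec * rec_inc)

  k <- min(50L, length(ys))
  denom <- min(50L, npos)
  ap50 <- sum(prec[seq_len(k)] * ys[seq_len(k)]) / denom

  list(f1 = f1, auc = auc, auprc = auprc, ap50 = ap50)
}

#' Fit and evaluate a classifier across cross-validation folds
#'
#' For every fold, fits the classifier on the training indices, scores the
#' test indices, and computes F1 (threshold 0.5 on the positive-class
#' probability) and AUC. Folds with a single-class test set (always the
#' case for leave-one-out) contribute to the pooled metrics instead:
#' per-fold AUC is skipped and one pooled F1/AUC over all held-out
#' predictions is reported.
#'
#' @param features Numeric feature matrix.
#' @param labels Vector of labels (+1/-1 or 1/0).
#' @param spec A [classifier_spec()].
#' @param folds Folds from [make_cv_splits()].
#' @param seed Seed forwarded to stochastic classifiers.
#' @param test_features,test_labels For cross-dataset folds: the held-out
#'   dataset's features and labels (fold `test` indices then index these).
#' @return A list of class `metrics_report`: `per_fold` (data frame with
#'   `f1`, `auc`), `mean_f1`, `sd_f1`, `mean_auc`, `sd_auc`, `pooled`
#'   (metrics over all held-out predictions), `scores` (held-out scores),
#'   `labels`.
#' @export
train_eval <- function(features, labels, spec, folds, seed = 1L,
                       test_features = NULL, test_labels = NULL) {
  y <- as.integer(labels > 0)
  x_test_src <- if (is.null(test_features)) features else test_features
  y_test_src <- if (is.null(test_labels)) y else as.integer(test_labels > 0)

  all_scores <- rep(NA_real_, length(y_test_src))
  per_fold <- data.frame(f1 = numeric(0), auc = numeric(0))
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    predict_fn <- tryCatch(
      fit_classifier(spec, features[f$train, , drop = FALSE], y[f$train],
                     seed = seed),
      error = function(e) stop("fold ", fi, ": ", conditionMessage(e)))
    sc <- predict_fn(x_test_src[f$test, , drop = FALSE])
    all_scores[f$test] <- sc
    yt <- y_test_src[f$test]
    if (length(unique(yt)) == 2L) {
      m <- compute_metrics(yt, sc)
      per_fold <- rbind(per_fold, data.frame(f1 = m$f1, auc = m$auc))
    }
  }
  seen <- !is.na(all_scores)
  pooled <- compute_metrics(y_test_src[seen], all_scores[seen])
  structure(list(
    per_fold = per_fold,
    mean_f1 = if (nrow(per_fold)) mean(per_fold$f1) else pooled$f1,
    sd_f1 = if (nrow(per_fold) > 1L) sd(per_fold$f1) else 0,
    mean_auc = if (nrow(per_fold)) mean(per_fold$auc) else pooled$auc,
    sd_auc = if (nrow(per_fold) > 1L) sd(per_fold$auc) else 0,
    pooled = pooled, scores = all_scores, labels = y_test_src
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: F1 %.3f (SD %.3f), AUC %.3f (SD %.3f), %d folds\n",
              x$mean_f1, x$sd_f1, x$mean_auc, x$sd_auc, nrow(x$per_fold)))
  invisible(x)
}

#' Sample invalid polypharmacy triples
#'
#' Draws `n` distinct drug--side-effect--drug triples, with canonical
#' (lexicographic) drug ordering, that do not occur among the known valid
#' triples. Used to build label-0 examples, mirroring the benchmark
#' convention that invalid interactions are random combinations absent
#' from both train and test sets.
#'
#' @param known_triples Data frame with `drug1`, `side_effect`, `drug2`
#'   (the union of train and test valid triples).
#' @param n Number of negatives to draw.
#' @param drug_pool,side_effect_pool Candidate identifier vectors.
#' @param seed Integer seed.
#' @return Data frame with `drug1`, `side_effect`, `drug2`, `label = 0`.
#' @export
sample_negative_triples <- function(known_triples, n, drug_pool,
                                    side_effect_pool, seed = 1L) {
  drug_pool <- sort(unique(drug_pool))
  side_effect_pool <- sort(unique(side_effect_pool))
  nd <- length(drug_pool)
  n_space <- nd * (nd - 1) / 2 * length(side_effect_pool)
  known <- canonicalize_triples(known_triples)
  known_keys <- unique(paste(known$drug1, known$side_effect, known$drug2,
                             sep = "\r"))
  free <- n_space - length(known_keys)
  if (n > free) {
    stop("cannot draw ", n, " negatives: only ", free,
         " candidate triples remain")
  }
  with_seed(seed, {
    out_keys <- character(0)
    while (length(out_keys) < n) {
      m <- max(2L * (n - length(out_keys)), 32L)
      d1 <- drug_pool[sample.int(nd, m, replace = TRUE)]
      d2 <- drug_pool[sample.int(nd, m, replace = TRUE)]
      se <- side_effect_pool[sample.int(length(side_effect_pool), m,
                                        replace = TRUE)]
      keep <- d1 != d2
      lo <- pmin(d1[keep], d2[keep])
      hi <- pmax(d1[keep], d2[keep])
      keys <- paste(lo, se[keep], hi, sep = "\r")
      keys <- keys[!(keys %in% known_keys) & !(keys %in% out_keys)]
      out_keys <- c(out_keys, unique(keys))
    }
    out_keys <- out_keys[seq_len(n)]
    parts <- strsplit(out_keys, "\r", fixed = TRUE)
    data.frame(drug1 = vapply(parts, `[[`, "", 1L),
               side_effect = vapply(parts, `[[`, "", 2L),
               drug2 = vapply(parts, `[[`, "", 3L),
               label = 0L, stringsAsFactors = FALSE)
  })
}

#' Occurrence score of polypharmacy triples
#'
#' The occurrence score of a triple drug A--side effect--drug B is the
#' number of triples sharing the same (unordered) drug pair, regardless of
#' side effect. In the weighted polypharmacy convention this count plays
#' the role of the co-occurrence score, with subject and object scores set
#' to 1.
#'
#' @param triples Data frame with `drug1`, `side_effect`, `drug2`.
#' @return Integer vector of scores aligned with the rows of `triples`.
#' @export
compute_occurrence_scores <- function(triples) {
  tri <- canonicalize_triples(triples)
  key <- paste(tri$drug1, tri$drug2, sep = "\r")
  as.integer(stats::ave(seq_along(key), key, FUN = length))
}

#' Convert polypharmacy triples to triplet records for embedding training
#'
#' Subject and object mapping scores are set to 1; the co-occurrence field
#' carries the occurrence score of the drug pair.
#'
#' @param triples Data frame with `drug1`, `side_effect`, `drug2` (valid
#'   triples only).
#' @return Triplet record data frame in the [read_triplets()] layout.
#' @export
triples_to_records <- function(triples) {
  data.frame(subject_id = triples$drug1,
             predicate = triples$side_effect,
             object_id = triples$drug2,
             subject_score = 1,
             object_score = 1,
             cooccurrence = compute_occurrence_scores(triples),
             stringsAsFactors = FALSE)
}

#' Per-side-effect polypharmacy metrics
#'
#' Computes AUC, AUPRC, and AP@50 separately for each side effect present
#' in the test triples, then averages, following the polypharmacy
#' evaluation convention. Side effects whose test triples are single-class
#' are skipped.
#'
#' @param triples Labelled triple data frame (0/1 labels).
#' @param scores Predicted positive-class scores aligned with `triples`.
#' @return List with `per_side_effect` (data frame) and means/SDs
#'   `mean_auc`, `sd_auc`, `mean_auprc`, `sd_auprc`, `mean_ap50`,
#'   `sd_ap50`.
#' @export
per_side_effect_metrics <- function(triples, scores) {
  stopifnot(nrow(triples) == length(scores))
  rows <- lapply(split(seq_len(nrow(triples)), triples$side_effect),
                 function(idx) {
    yt <- triples$label[idx]
    if (length(unique(yt)) < 2L) return(NULL)
    m <- compute_metrics(yt, scores[idx])
    data.frame(side_effect = triples$side_effect[idx[1L]],
               auc = m$auc, auprc = m$auprc, ap50 = m$ap50)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop("no side effect with both classes")
  rownames(tab) <- NULL
  list(per_side_effect = tab,
       mean_auc = mean(tab$auc), sd_auc = if (nrow(tab) > 1) sd(tab$auc) else 0,
       mean_auprc = mean(tab$auprc),
       sd_auprc = if (nrow(tab) > 1) sd(tab$auprc) else 0,
       mean_ap50 = mean(tab$ap50),
       sd_ap50 = if (nrow(tab) > 1) sd(tab$ap50) else 0)
}
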