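#' Skip-gram negative-sampling parameters
#'
#' @param dimension Embedding dimension.
#' @param window Context window half-width; for each center token the
#'   trainer samples a shrunken window in `1..window` per the usual SGNS
#'   scheme.
#' @param alpha Initial learning rate, decayed linearly over training.
#' @param negative_samples Noise tokens per positive (unigram^0.75
#'   distribution).
#' @param epochs Passes over the corpus.
#' @param min_count Drop tokens occurring fewer than `min_count` times.
#'   Default 0: every graph vertex keeps an embedding, so downstream
#'   benchmark concepts are never lost to frequency pruning.
#' @param seed Integer seed; training is single-threaded and deterministic.
#' @return A list of class `sgns_params`.
#' @export
sgns_params <- function(dimension = 128L, window = 4L, alpha = 0.025,
                        negative_samples = 5L, epochs = 5L, min_count = 0L,
                        seed = 1L) {
  stopifnot(dimension >= 1L, window >= 1L, alpha > 0, negative_samples >= 0L,
            epochs >= 1L, min_count >= 0L)
  structure(list(dimension = as.integer(dimension),
                 window = as.integer(window), alpha = alpha,
                 negative_samples = as.integer(negative_samples),
                 epochs = as.integer(epochs),
                 min_count = as.integer(min_count), seed = as.integer(seed)),
            class = "sgns_params")
}

#' Train skip-gram negative-sampling embeddings from a walk corpus
#'
#' The trainer is a bespoke single-threaded SGNS implementation: for every
#' (center, context) token pair within the window it performs one positive
#' logistic update and `negative_samples` noise updates, with a linearly
#' decaying learning rate. Deterministic given the seed.
#'
#' @param corpus A `walk_corpus` (see [generate_walks()]).
#' @param params An [sgns_params()].
#' @return Numeric matrix, one row per retained token (rownames are tokens).
#' @export
train_sgns <- function(corpus, params = sgns_params()) {
  stopifnot(inherits(corpus, "walk_corpus"), inherits(params, "sgns_params"))
  if (!length(corpus$sequences) || !sum(lengths(corpus$sequences))) {
    stop("empty corpus")
  }
  tokens <- unlist(corpus$sequences, use.names = FALSE)
  counts <- table(tokens)
  vocab <- names(counts)[as.vector(counts) >= params$min_count]
  if (!length(vocab)) stop("empty vocabulary after min_count filtering")
  vocab <- sort(vocab)
  idx <- stats::setNames(seq_along(vocab), vocab)
  sents <- lapply(corpus$sequences, function(s) {
    m <- idx[s]
    as.integer(m[!is.na(m)]) - 1L
  })
  sents <- sents[lengths(sents) > 0L]
  freq <- as.numeric(table(factor(tokens, levels = vocab)))
  mat <- .sgns_train_cpp(sents, length(vocab), freq, params$dimension,
                         params$window, params$alpha,
                         params$negative_samples, params$epochs, params$seed)
  rownames(mat) <- vocab
  mat
}

#' L2-normalize an embedding table
#'
#' Divides every row by its Euclidean norm so all vectors lie on the unit
#' sphere; cosine similarity between normalized vectors is then their dot
#' product. Idempotent.
#'
#' @param table Numeric matrix with identifier rownames.
#' @return The normalized matrix, with attribute `normalized = TRUE`.
#' @export
l2_normalize <- function(table) {
  stopifnot(is.matrix(table), is.numeric(table))
  norms <- sqrt(rowSums(table^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    stop("cannot L2-normalize zero vector for token: ",
         paste(rownames(table)[zero], collapse = ", "))
  }
  out <- table / norms
  attr(out, "normalized") <- TRUE
  out
}

#' Named hyperparameter profiles
#'
#' Bundled settings for the two task profiles used throughout the package:
#' drug--ADE prediction and polypharmacy prediction, each for the walk+SGNS
#' route and the TransE route. The `semmeddb_augmented` TransE profile
#' targets very large graphs and is intended for cluster-scale runs.
#'
#' @param name One of `"drug_ade_deepwalk"`, `"polypharmacy_deepwalk"`,
#'   `"drug_ade_transe"`, `"polypharmacy_transe"`, `"semmeddb_transe"`.
#' @param seed Seed stored into the returned parameter objects.
#' @return For DeepWalk profiles, a list with `walk` ([walk_params()]) and
#'   `sgns` ([sgns_params()]); for TransE profiles a [transe_params()].
#' @export
profile_params <- function(name = c("drug_ade_deepwalk",
                                    "polypharmacy_deepwalk",
                                    "drug_ade_transe",
                                    "polypharmacy_transe",
                                    "semmeddb_transe"),
                           seed = 1L) {
  name <- match.arg(name)
  switch(name,
    drug_ade_deepwalk = list(
      walk = walk_params(num_walks_per_vertex = 20L, walk_length = 500L,
                         seed = seed),
      sgns = sgns_params(dimension = 256L, window = 4L, alpha = 0.025,
                         seed = seed)),
    polypharmacy_deepwalk = list(
      walk = walk_params(num_walks_per_vertex = 25L, walk_length = 500L,
                         seed = seed),
      sgns = sgns_params(dimension = 256L, window = 10L, alpha = 0.025,
                         seed = seed)),
    drug_ade_transe = transe_params(dimension = 100L, alpha = 0.001,
                                    batch_size = 256L, epochs = 100L,
                                    negatives_per_positive = 1L, seed = seed),
    polypharmacy_transe = transe_params(dimension = 100L, alpha = 0.001,
                                        batch_size = 512L, epochs = 100L,
                                        negatives_per_positive = 1L,
                                        seed = seed),
    semmeddb_transe = transe_params(dimension = 100L, alpha = 0.001,
                                    batch_size = 512L, epochs = 1500L,
                                    negatives_per_positive = 2L, seed = seed))
}
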