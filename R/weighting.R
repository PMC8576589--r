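#' Triplet weighting parameters
#'
#' The raw confidence weight of a triplet is the product
#' `(w_j * s_subj) * (w_i * s_obj) * (w_p * c)`, where `s_subj` and `s_obj`
#' are the NLP mapping scores of the subject and object concepts and `c` is
#' the co-occurrence count. The three multipliers let the user rebalance the
#' contribution of each score; the defaults leave them equal.
#'
#' @param w_subject,w_object,w_predicate Nonnegative multipliers for the
#'   subject score, object score and co-occurrence count.
#' @param score_floor Small positive floor applied to each score before
#'   multiplication, so zero scores never yield zero weights (a later
#'   division by the normalized weight must stay finite).
#' @param temperature Positive softmax temperature used when turning
#'   normalized scores into sampling probabilities.
#' @return A list of class `weight_params`.
#' @export
weight_params <- function(w_subject = 1, w_object = 1, w_predicate = 1,
                          score_floor = 1e-6, temperature = 1) {
  if (any(c(w_subject, w_object, w_predicate) < 0)) {
    stop("score multipliers must be nonnegative")
  }
  stopifnot(score_floor > 0, temperature > 0)
  structure(list(w_subject = w_subject, w_object = w_object,
                 w_predicate = w_predicate, score_floor = score_floor,
                 temperature = temperature),
            class = "weight_params")
}

#' Raw confidence weight of triplet records
#'
#' Computes `W = (w_j * max(s_subj, floor)) * (w_i * max(s_obj, floor)) *
#' (w_p * max(c, floor))` for each record. Vectorized over rows.
#'
#' @param records Triplet data frame (one or more rows).
#' @param params A [weight_params()].
#' @return Numeric vector of nonnegative raw weights.
#' @export
raw_weight <- function(records, params = weight_params()) {
  validate_triplets(records)
  fl <- params$score_floor
  (params$w_subject * pmax(records$subject_score, fl)) *
    (params$w_object * pmax(records$object_score, fl)) *
    (params$w_predicate * pmax(records$cooccurrence, fl))
}

#' Max-normalize raw weights
#'
#' Divides every raw weight by the global maximum so the normalized scores
#' lie in (0, 1] with maximum exactly 1. The global (whole-graph) maximum is
#' used so that scores remain comparable across neighbourhoods and the very
#' large raw products are tamed before any exponentiation.
#'
#' @param raw_weights Nonnegative numeric vector, at least one positive.
#' @return Numeric vector of the same length in (0, 1].
#' @export
normalize_scores <- function(raw_weights) {
  if (!length(raw_weights)) stop("no raw weights to normalize")
  m <- max(raw_weights)
  if (!is.finite(m) || m <= 0) stop("maximum raw weight must be positive")
  raw_weights / m
}

#' Softmax sampling distribution
#'
#' Converts scores into probabilities, `p_k = exp(f_k / T) / sum_m
#' exp(f_m / T)`, computed with the max-shift trick for numerical stability.
#'
#' @param f_values Numeric vector of scores.
#' @param temperature Positive temperature `T`.
#' @return Probability vector summing to 1.
#' @export
softmax_distribution <- function(f_values, temperature = 1) {
  if (!length(f_values)) stop("empty score vector")
  stopifnot(temperature > 0)
  z <- f_values / temperature
  e <- exp(z - max(z))
  e / sum(e)
}

#' Score every aggregated triplet of a graph
#'
#' Attaches a normalized confidence score `f` in (0, 1] to each aggregated
#' triplet: the raw product weight divided by the global maximum over the
#' graph. The result feeds the confidence-biased walker and Weighted TransE.
#'
#' @param graph A `kg_graph`.
#' @param params A [weight_params()].
#' @return The graph with an extra element `scores`: a list holding
#'   `raw` and `f` (per aggregated triplet, aligned with `graph$edges`)
#'   and the `params` used.
#' @export
score_graph <- function(graph, params = weight_params()) {
  stopifnot(inherits(graph, "kg_graph"))
  raw <- raw_weight(graph$edges, params)
  graph$scores <- list(raw = raw, f = normalize_scores(raw), params = params)
  graph
}

#' Grid search over score multipliers
#'
#' Evaluates candidate (subject, object, co-occurrence) multiplier triples
#' by downstream classification performance and returns the best. The
#' evaluation function receives a scored graph and must return a single
#' numeric score (for example a cross-validated F1 or AUC); larger is
#' better.
#'
#' @param graph A `kg_graph`.
#' @param candidates Data frame with columns `w_subject`, `w_object`,
#'   `w_predicate`; one row per candidate.
#' @param eval_fn Function `(scored_graph) -> numeric(1)`.
#' @param ... Further arguments passed to [weight_params()].
#' @return List with `best` (a `weight_params`), `results` (candidates plus
#'   a `score` column).
#' @export
tune_weights <- function(graph, candidates, eval_fn, ...) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L,
            all(c("w_subject", "w_object", "w_predicate") %in%
                  names(candidates)))
  scores <- vapply(seq_len(nrow(candidates)), function(i) {
    p <- weight_params(w_subject = candidates$w_subject[i],
                       w_object = candidates$w_object[i],
                       w_predicate = candidates$w_predicate[i], ...)
    eval_fn(score_graph(graph, p))
  }, numeric(1))
  results <- cbind(candidates, score = scores)
  best <- candidates[which.max(scores), ]
  list(best = weight_params(w_subject = best$w_subject,
                            w_object = best$w_object,
                            w_predicate = best$w_predicate, ...),
       results = results)
}
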