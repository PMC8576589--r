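#' TransE training parameters
#'
#' @param dimension Embedding dimension `k`.
#' @param margin Margin hyperparameter of the ranking loss (> 0).
#' @param norm Dissimilarity: `"L2"` (default) or `"L1"`.
#' @param alpha SGD learning rate.
#' @param batch_size Minibatch size in triplets.
#' @param epochs Passes over the training set.
#' @param negatives_per_positive Corrupted triplets drawn per positive.
#' @param f_min Confidence floor: triplet confidences are clipped to
#'   `[f_min, 1]` before the energy division, so `1/f` stays bounded.
#' @param seed Integer seed.
#' @return A list of class `transe_params`.
#' @export
transe_params <- function(dimension = 100L, margin = 1, norm = c("L2", "L1"),
                          alpha = 0.001, batch_size = 256L, epochs = 100L,
                          negatives_per_positive = 1L, f_min = 1e-3,
                          seed = 1L) {
  norm <- match.arg(norm)
  stopifnot(dimension >= 1L, margin > 0, alpha > 0, batch_size >= 1L,
            epochs >= 1L, negatives_per_positive >= 1L,
            f_min > 0, f_min <= 1)
  structure(list(dimension = as.integer(dimension), margin = margin,
                 norm = norm, alpha = alpha,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 negatives_per_positive = as.integer(negatives_per_positive),
                 f_min = f_min, seed = as.integer(seed)),
            class = "transe_params")
}

#' Energy of a triplet
#'
#' `d(h + l, t)`: the L1 or L2 norm of the translation residual
#' `h + l - t`. Low energy means the relation is well modelled as a
#' translation from head to tail.
#'
#' @param h_vec,l_vec,t_vec Numeric vectors of equal length.
#' @param norm `"L2"` or `"L1"`.
#' @return Nonnegative scalar.
#' @export
energy <- function(h_vec, l_vec, t_vec, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  if (length(h_vec) != length(l_vec) || length(l_vec) != length(t_vec)) {
    stop("dimension mismatch between head, relation, and tail vectors")
  }
  r <- h_vec + l_vec - t_vec
  if (norm == "L1") sum(abs(r)) else sqrt(sum(r^2))
}

#' Corrupt a training triplet
#'
#' Replaces either the head or the tail (with equal probability, never
#' both, never the relation) by an entity drawn uniformly from the pool,
#' different from the one it replaces. Uses R's RNG stream.
#'
#' @param triplet List or one-row data frame with `head`, `relation`,
#'   `tail`.
#' @param entity_pool Character vector of candidate entities (>= 2).
#' @return List with `head`, `relation`, `tail`, and `corrupted`
#'   (`"head"` or `"tail"`).
#' @export
corrupt <- function(triplet, entity_pool) {
  if (length(unique(entity_pool)) < 2L) {
    stop("entity pool must contain at least two distinct entities")
  }
  side <- if (runif(1) < 0.5) "head" else "tail"
  orig <- if (side == "head") triplet$head else triplet$tail
  cand <- setdiff(unique(entity_pool), orig)
  repl <- cand[sample.int(length(cand), 1L)]
  out <- list(head = triplet$head, relation = triplet$relation,
              tail = triplet$tail, corrupted = side)
  out[[side]] <- repl
  out
}

#' Margin-ranking loss over aligned positive/negative triplets
#'
#' Computes `sum_i [margin + d(h_i + l_i, t_i) / f_i - d(h'_i + l_i, t'_i)]_+`
#' where `f_i` is the positive triplet's confidence, clipped to
#' `[f_min, 1]`. With every `f_i = 1` this is exactly the unweighted TransE
#' loss. The ablation `weighting = "multiply"` replaces the division by a
#' multiplication.
#'
#' @param positives Data frame with columns `head`, `relation`, `tail` and
#'   optionally `confidence` (default 1).
#' @param negatives Data frame aligned row-by-row with `positives`.
#' @param entities,relations Embedding matrices with identifier rownames.
#' @param params A [transe_params()].
#' @param weighting `"divide"` (default), `"multiply"` (ablation), or
#'   `"none"` (force unweighted).
#' @return Nonnegative scalar loss.
#' @export
margin_loss <- function(positives, negatives, entities, relations,
                        params = transe_params(),
                        weighting = c("divide", "multiply", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(nrow(positives) == nrow(negatives))
  conf <- if (!is.null(positives$confidence)) positives$confidence
          else rep(1, nrow(positives))
  if (any(conf <= 0) || any(conf > 1)) {
    stop("confidences must lie in (0, 1]")
  }
  conf <- pmin(pmax(conf, params$f_min), 1)
  d <- function(hh, ll, tt) {
    vapply(seq_along(hh), function(i) {
      energy(entities[hh[i], ], relations[ll[i], ], entities[tt[i], ],
             params$norm)
    }, numeric(1))
  }
  d_pos <- d(positives$head, positives$relation, positives$tail)
  d_neg <- d(negatives$head, negatives$relation, negatives$tail)
  d_pos_w <- switch(weighting,
                    divide = d_pos / conf,
                    multiply = d_pos * conf,
                    none = d_pos)
  sum(pmax(params$margin + d_pos_w - d_neg, 0))
}

#' Train TransE or Weighted TransE embeddings
#'
#' Minibatch SGD on the margin-ranking loss with uniformly corrupted
#' negatives ("raw" negative sampling: corrupted triplets that happen to be
#' true are not filtered out). Entity embeddings are renormalized to unit
#' L2 after every update step. In the weighted variant each positive
#' triplet's energy is divided by its confidence `f` (clipped to
#' `[f_min, 1]`); unweighted training uses `f = 1` for every triplet and is
#' arithmetically identical to the classic formulation. Initialization is
#' uniform in `[-6/sqrt(k), 6/sqrt(k)]`. Reproducible given the seed.
#'
#' @param triplets Data frame with columns `head`, `relation`, `tail`, and
#'   optionally `confidence` in (0, 1] (ignored unless
#'   `weighted = TRUE`).
#' @param params A [transe_params()].
#' @param weighted Logical: divide positive energies by confidence?
#' @param weighting Energy reweighting mode when `weighted = TRUE`:
#'   `"divide"` (the default formulation) or `"multiply"` (ablation).
#' @return List of class `transe_model` with `entities` and `relations`
#'   embedding matrices (identifier rownames) and `loss` (per-epoch mean
#'   hinge loss).
#' @export
train_transe <- function(triplets, params = transe_params(),
                         weighted = FALSE,
                         weighting = c("divide", "multiply")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(triplets))
  if (!nrow(triplets)) stop("empty training set")
  need <- c("head", "relation", "tail")
  if (!all(need %in% names(triplets))) {
    stop("triplets need columns head, relation, tail")
  }
  ents <- sort(unique(c(triplets$head, triplets$tail)))
  rels <- sort(unique(triplets$relation))
  ei <- stats::setNames(seq_along(ents), ents)
  ri <- stats::setNames(seq_along(rels), rels)
  conf <- if (weighted && !is.null(triplets$confidence)) {
    pmin(pmax(triplets$confidence, params$f_min), 1)
  } else rep(1, nrow(triplets))
  if (any(!is.finite(conf)) || any(conf <= 0)) stop("invalid confidences")
  fit <- .transe_train_cpp(
    as.integer(ei[triplets$head]) - 1L,
    as.integer(ri[triplets$relation]) - 1L,
    as.integer(ei[triplets$tail]) - 1L,
    as.numeric(conf), length(ents), length(rels),
    params$dimension, params$margin, if (params$norm == "L1") 1L else 2L,
    params$alpha, params$batch_size, params$epochs,
    params$negatives_per_positive,
    if (weighted && weighting == "multiply") 1L else 0L,
    params$seed)
  rownames(fit$entities) <- ents
  rownames(fit$relations) <- rels
  structure(list(entities = fit$entities, relations = fit$relations,
                 loss = as.numeric(fit$loss), params = params,
                 weighted = weighted), class = "transe_model")
}

#' @export
print.transe_model <- function(x, ...) {
  cat(sprintf("transe_model: %d entities, %d relations, dim %d, %s%s\n",
              nrow(x$entities), nrow(x$relations), x$params$dimension,
              if (x$weighted) "weighted" else "unweighted",
              sprintf(", final mean loss %.4f", x$loss[length(x$loss)])))
  invisible(x)
}

#' Rank the true tail among all candidate tails
#'
#' For each triplet, scores every candidate entity as tail by energy and
#' returns the rank of the true tail (1 = lowest energy). With
#' `filtered = TRUE` other known true tails for the same (head, relation)
#' are excluded from the candidate list before ranking.
#'
#' @param model A `transe_model`.
#' @param triplets Data frame with `head`, `relation`, `tail`.
#' @param filtered Logical; default `FALSE` (raw ranks).
#' @return Integer vector of ranks, one per triplet.
#' @export
tail_ranks <- function(model, triplets, filtered = FALSE) {
  ents <- model$entities
  rels <- model$relations
  known <- paste(triplets$head, triplets$relation, triplets$tail, sep = "\r")
  vapply(seq_len(nrow(triplets)), function(i) {
    hv <- ents[triplets$head[i], ] + rels[triplets$relation[i], ]
    d <- sqrt(rowSums(sweep(ents, 2L, hv)^2))
    if (model$params$norm == "L1") {
      d <- rowSums(abs(sweep(ents, 2L, hv)))
    }
    if (filtered) {
      others <- paste(triplets$head[i], triplets$relation[i],
                      rownames(ents), sep = "\r") %in% known &
        rownames(ents) != triplets$tail[i]
      d[others] <- Inf
    }
    as.integer(rank(d, ties.method = "average")[triplets$tail[i]])
  }, integer(1))
}

#' Mean energies of triplets under a trained model
#'
#' @param model A `transe_model`.
#' @param triplets Data frame with `head`, `relation`, `tail`.
#' @return Numeric vector of energies, one per triplet.
#' @export
triplet_energies <- function(model, triplets) {
  vapply(seq_len(nrow(triplets)), function(i) {
    energy(model$entities[triplets$head[i], ],
           model$relations[triplets$relation[i], ],
           model$entities[triplets$tail[i], ], model$params$norm)
  }, numeric(1))
}

#' Training triplets (with confidences) from a scored graph
#'
#' Converts the aggregated triplets of a scored graph into the TransE
#' training layout: head, relation, tail, confidence = normalized score f.
#'
#' @param graph A scored `kg_graph` (see [score_graph()]).
#' @return Data frame with columns `head`, `relation`, `tail`,
#'   `confidence`.
#' @export
graph_to_triplets <- function(graph) {
  stopifnot(inherits(graph, "kg_graph"))
  out <- data.frame(head = graph$edges$subject_id,
                    relation = graph$edges$predicate,
                    tail = graph$edges$object_id,
                    stringsAsFactors = FALSE)
  if (!is.null(graph$scores)) out$confidence <- graph$scores$f
  out
}
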