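#' Random-walk parameters
#'
#' @param num_walks_per_vertex Number of walks started at every vertex (N).
#' @param walk_length Maximum number of vertices per walk (L).
#' @param seed Integer seed; walks are reproducible given the seed.
#' @param sampler `"uniform"` (plain DeepWalk) or `"weighted"`
#'   (confidence-biased: next step drawn from a softmax over the normalized
#'   triplet scores of the current neighbourhood).
#' @param emit_predicates If `TRUE`, predicate tokens (prefixed `"p:"`) are
#'   interleaved between vertex tokens in the corpus. Default `FALSE`:
#'   embeddings are learned for concepts only.
#' @return A list of class `walk_params`.
#' @export
walk_params <- function(num_walks_per_vertex = 10L, walk_length = 40L,
                        seed = 1L, sampler = c("uniform", "weighted"),
                        emit_predicates = FALSE) {
  sampler <- match.arg(sampler)
  stopifnot(num_walks_per_vertex >= 1L, walk_length >= 1L)
  structure(list(num_walks_per_vertex = as.integer(num_walks_per_vertex),
                 walk_length = as.integer(walk_length),
                 seed = as.integer(seed), sampler = sampler,
                 emit_predicates = isTRUE(emit_predicates)),
            class = "walk_params")
}

#' Draw the next (predicate, vertex) step uniformly
#'
#' Each adjacency entry of `v` -- a (predicate, neighbour) pair -- is equally
#' likely, with probability `1/|H(v)|`. Uses R's RNG stream.
#'
#' @param graph A `kg_graph`.
#' @param v Vertex identifier.
#' @return List with `predicate` and `vertex`, or `NULL` for a dead end.
#' @export
uniform_next <- function(graph, v) {
  nb <- neighborhood(graph, v)
  if (!nrow(nb)) return(NULL)
  k <- sample.int(nrow(nb), 1L)
  list(predicate = nb$predicate[k], vertex = nb$neighbor[k])
}

#' Draw the next (predicate, vertex) step biased by confidence
#'
#' The entry is sampled from a softmax over the normalized triplet scores of
#' `v`'s neighbourhood, so high-confidence triplets are favoured. Two entries
#' reaching the same neighbour through different predicates are distinct
#' outcomes.
#'
#' @param graph A scored `kg_graph` (see [score_graph()]).
#' @param v Vertex identifier.
#' @return List with `predicate` and `vertex`, or `NULL` for a dead end.
#' @export
weighted_next <- function(graph, v) {
  if (is.null(graph$scores)) stop("graph has no scores; call score_graph()")
  nb <- neighborhood(graph, v)
  if (!nrow(nb)) return(NULL)
  f <- graph$scores$f[nb$edge_id]
  if (anyNA(f)) stop("missing normalized score for an adjacency entry of ", v)
  p <- softmax_distribution(f, graph$scores$params$temperature)
  k <- sample.int(nrow(nb), 1L, prob = p)
  list(predicate = nb$predicate[k], vertex = nb$neighbor[k])
}

#' Generate a random-walk corpus
#'
#' Starts `N` truncated random walks of up to `L` vertices at every vertex.
#' The uniform sampler reproduces DeepWalk's next-step rule (probability
#' `1/|H(v)|` per (predicate, neighbour) entry); the weighted sampler biases
#' each step toward high-confidence triplets through a softmax over
#' normalized scores. Walks that reach a vertex with no outgoing entries
#' (possible in directed mode only) stop early. Each walk uses its own RNG
#' stream derived from (seed, start vertex, walk index), so the corpus is
#' reproducible and independent of iteration order.
#'
#' @param graph A `kg_graph`; must be scored (see [score_graph()]) when
#'   `params$sampler == "weighted"`.
#' @param params A [walk_params()].
#' @return A list of class `walk_corpus` with `sequences` (list of character
#'   vectors) and `vocabulary` (sorted unique tokens).
#' @export
generate_walks <- function(graph, params = walk_params()) {
  stopifnot(inherits(graph, "kg_graph"), inherits(params, "walk_params"))
  weighted <- params$sampler == "weighted"
  if (weighted && is.null(graph$scores)) {
    stop("weighted sampler requires a scored graph; call score_graph()")
  }
  nv <- length(graph$vertices)
  emit_p <- params$emit_predicates

  # flat adjacency, grouped by source vertex
  ord <- order(graph$adj$from)
  from_sorted <- graph$adj$from[ord]
  adj_to <- as.integer(graph$adj$to[ord])
  adj_pred <- as.integer(graph$adj$pred[ord])
  counts <- tabulate(from_sorted, nbins = nv)
  adj_start <- as.integer(c(0L, cumsum(counts)))
  cum <- numeric(0)
  if (weighted) {
    f_entry <- graph$scores$f[graph$adj$edge_id[ord]]
    temp <- graph$scores$params$temperature
    cum <- unlist(lapply(seq_len(nv), function(v) {
      idx <- if (counts[v] > 0L) (adj_start[v] + 1L):adj_start[v + 1L]
             else integer(0)
      if (!length(idx)) return(numeric(0))
      cumsum(softmax_distribution(f_entry[idx], temp))
    }), use.names = FALSE)
  }
  raw <- .walk_corpus_cpp(adj_to, adj_pred, adj_start, cum,
                          params$num_walks_per_vertex, params$walk_length,
                          params$seed)
  sequences <- lapply(raw, function(w) {
    len <- nrow(w)
    toks <- graph$vertices[w[, 1L]]
    if (emit_p && len > 1L) {
      preds <- paste0("p:", graph$predicates[w[2:len, 2L]])
      out <- character(2L * len - 1L)
      out[seq(1L, 2L * len - 1L, by = 2L)] <- toks
      out[seq(2L, 2L * len - 2L, by = 2L)] <- preds
      out
    } else toks
  })
  structure(list(sequences = sequences,
                 vocabulary = sort(unique(unlist(sequences)))),
            class = "walk_corpus")
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("walk_corpus: %d sequences, %d tokens, vocabulary %d\n",
              length(x$sequences), sum(lengths(x$sequences)),
              length(x$vocabulary)))
  invisible(x)
}

#' Write a walk corpus to a text file
#'
#' One walk per line, space-separated tokens.
#'
#' @param corpus A `walk_corpus`.
#' @param path Output path.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "walk_corpus"))
  writeLines(vapply(corpus$sequences, paste, "", collapse = " "), path)
  invisible(path)
}

#' Read a walk corpus from a text file
#'
#' @param path Path to a corpus written by [write_corpus()].
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  seqs <- strsplit(lines, " ", fixed = TRUE)
  structure(list(sequences = seqs,
                 vocabulary = sort(unique(unlist(seqs)))),
            class = "walk_corpus")
}
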