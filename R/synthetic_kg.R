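#' Configuration for the synthetic noisy knowledge-graph generator
#'
#' The generator plants a block structure: drugs, diseases, and filler
#' concepts are partitioned into `n_blocks` communities, and true triplets
#' connect vertices within a block. Spurious triplets connect uniformly
#' random vertex pairs. Confidence metadata is truth-correlated: true
#' triplets draw high subject/object mapping scores and co-occurrence
#' counts, spurious triplets draw from a low regime, emulating the way NLP
#' extraction noise manifests in literature-derived triplet stores. The
#' spurious fraction is budgeted exactly (`round(noise_rate * n_triplets)`
#' triplets), not Bernoulli-sampled.
#'
#' @param n_drugs,n_diseases,n_filler_concepts Vertex counts per type.
#' @param n_predicates Number of relation labels; predicate 1
#'   (`"CAUSES"`-like) is reserved for drug--disease edges.
#' @param n_blocks Number of planted communities.
#' @param edges_per_vertex Average triplet budget per vertex.
#' @param noise_rate Fraction of spurious triplets in `[0, 1)`.
#' @param score_model List with elements `true_score_range`,
#'   `spurious_score_range` (uniform ranges for mapping scores) and
#'   `true_cooc_lambda`, `spurious_cooc_lambda` (co-occurrence is
#'   `1 + Poisson(lambda)`).
#' @param n_benchmark_pairs Number of labelled drug--disease benchmark
#'   pairs to derive (balanced between classes).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 50L, n_diseases = 10L,
                         n_filler_concepts = 100L, n_predicates = 4L,
                         n_blocks = 5L, edges_per_vertex = 8,
                         noise_rate = 0.3,
                         score_model = list(
                           true_score_range = c(600, 1000),
                           spurious_score_range = c(50, 400),
                           true_cooc_lambda = 8,
                           spurious_cooc_lambda = 1),
                         n_benchmark_pairs = 200L, seed = 1L) {
  stopifnot(n_drugs >= 1L, n_diseases >= 1L, n_filler_concepts >= 0L,
            n_predicates >= 1L, n_blocks >= 1L, edges_per_vertex > 0,
            noise_rate >= 0, noise_rate < 1,
            n_blocks <= min(n_drugs, n_diseases))
  structure(list(n_drugs = as.integer(n_drugs),
                 n_diseases = as.integer(n_diseases),
                 n_filler_concepts = as.integer(n_filler_concepts),
                 n_predicates = as.integer(n_predicates),
                 n_blocks = as.integer(n_blocks),
                 edges_per_vertex = edges_per_vertex,
                 noise_rate = noise_rate, score_model = score_model,
                 n_benchmark_pairs = as.integer(n_benchmark_pairs),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic noisy knowledge graph
#'
#' Produces triplet records with truth-correlated confidence scores, a
#' per-triplet truth flag (test-only; never consumed by the learning
#' pipeline), and a labelled drug--disease benchmark derived from block
#' membership (positive iff the drug and disease share a block). True
#' triplets are laid out so every vertex receives at least one within-block
#' edge (a connectivity pass), with the remaining true budget filled by
#' random within-block pairs; drug--disease edges use predicate
#' `PRED1`, other within-block edges draw uniformly from the remaining
#' predicates (or `PRED1` itself when it is the only one).
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_output` with `triplets`, `truth_flags`,
#'   `benchmark_pairs`, `blocks` (per-vertex block assignment), and
#'   `config`.
#' @export
generate_synth_kg <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  drugs <- sprintf("DRUG%03d", seq_len(config$n_drugs))
  diseases <- sprintf("DIS%03d", seq_len(config$n_diseases))
  fillers <- if (config$n_filler_concepts > 0L) {
    sprintf("FILL%03d", seq_len(config$n_filler_concepts))
  } else character(0)
  vertices <- c(drugs, diseases, fillers)
  nv <- length(vertices)
  preds <- sprintf("PRED%d", seq_len(config$n_predicates))
  other_preds <- if (config$n_predicates > 1L) preds[-1L] else preds

  n_total <- round(config$edges_per_vertex * nv)
  n_spurious <- round(config$noise_rate * n_total)
  n_true <- n_total - n_spurious
  if (n_true < nv) {
    stop("edge budget infeasible: ", n_true,
         " true triplets cannot cover ", nv, " vertices")
  }

  with_seed(config$seed, {
    block_of <- stats::setNames(
      c(rep_len(seq_len(config$n_blocks), config$n_drugs),
        rep_len(seq_len(config$n_blocks), config$n_diseases),
        rep_len(seq_len(config$n_blocks), max(config$n_filler_concepts, 0L))),
      vertices)[seq_len(nv)]
    names(block_of) <- vertices
    members <- split(vertices, block_of)

    pick_partner <- function(v) {
      pool <- setdiff(members[[as.character(block_of[[v]])]], v)
      if (!length(pool)) return(NA_character_)
      pool[sample.int(length(pool), 1L)]
    }
    pick_pred <- function(s, o) {
      is_dd <- (s %in% drugs && o %in% diseases) ||
        (s %in% diseases && o %in% drugs)
      if (is_dd) preds[1L]
      else other_preds[sample.int(length(other_preds), 1L)]
    }

    seen <- character(0)
    subj <- character(n_true); pr <- character(n_true); obj <- character(n_true)
    k <- 0L
    add_edge <- function(s, o) {
      if (is.na(o) || s == o) return(FALSE)
      # drug->disease edges oriented drug first; otherwise as drawn
      if (o %in% drugs && s %in% diseases) { tmp <- s; s <- o; o <- tmp }
      p <- pick_pred(s, o)
      key <- paste(s, p, o, sep = "\r")
      if (key %in% seen) return(FALSE)
      k <<- k + 1L
      subj[k] <<- s; pr[k] <<- p; obj[k] <<- o
      seen <<- c(seen, key)
      TRUE
    }
    # connectivity pass: one within-block edge per vertex
    for (v in vertices) {
      for (attempt in 1:20) if (add_edge(v, pick_partner(v))) break
    }
    guard <- 0L
    while (k < n_true && guard < 200L * n_true) {
      guard <- guard + 1L
      s <- vertices[sample.int(nv, 1L)]
      add_edge(s, pick_partner(s))
    }
    if (k < n_true) {
      stop("edge budget infeasible: blocks too small for ", n_true,
           " distinct true triplets")
    }

    # spurious: uniformly random vertex pairs, any predicate
    sp_subj <- character(n_spurious); sp_pr <- character(n_spurious)
    sp_obj <- character(n_spurious)
    j <- 0L
    guard <- 0L
    while (j < n_spurious && guard < 200L * max(n_spurious, 1L)) {
      guard <- guard + 1L
      s <- vertices[sample.int(nv, 1L)]
      o <- vertices[sample.int(nv, 1L)]
      if (s == o) next
      p <- preds[sample.int(length(preds), 1L)]
      key <- paste(s, p, o, sep = "\r")
      if (key %in% seen) next
      j <- j + 1L
      sp_subj[j] <- s; sp_pr[j] <- p; sp_obj[j] <- o
      seen <- c(seen, key)
    }
    if (j < n_spurious) stop("edge budget infeasible for spurious triplets")

    sm <- config$score_model
    runif_in <- function(n, range) runif(n, range[1L], range[2L])
    triplets <- data.frame(
      subject_id = c(subj, sp_subj),
      predicate = c(pr, sp_pr),
      object_id = c(obj, sp_obj),
      subject_score = c(runif_in(n_true, sm$true_score_range),
                        runif_in(n_spurious, sm$spurious_score_range)),
      object_score = c(runif_in(n_true, sm$true_score_range),
                       runif_in(n_spurious, sm$spurious_score_range)),
      cooccurrence = c(1 + rpois(n_true, sm$true_cooc_lambda),
                       1 + rpois(n_spurious, sm$spurious_cooc_lambda)),
      stringsAsFactors = FALSE)
    truth_flags <- rep(c(TRUE, FALSE), c(n_true, n_spurious))

    # benchmark pairs: balanced positives (same block) and negatives
    all_pairs <- expand.grid(drug_id = drugs, disease_id = diseases,
                             stringsAsFactors = FALSE)
    same_block <- block_of[all_pairs$drug_id] == block_of[all_pairs$disease_id]
    n_half <- config$n_benchmark_pairs %/% 2L
    pos_idx <- which(same_block)
    neg_idx <- which(!same_block)
    if (length(pos_idx) < n_half || length(neg_idx) < n_half) {
      stop("not enough drug x disease pairs for the requested benchmark size")
    }
    pos <- all_pairs[pos_idx[sample.int(length(pos_idx), n_half)], ]
    neg <- all_pairs[neg_idx[sample.int(length(neg_idx), n_half)], ]
    benchmark <- rbind(cbind(pos, label = 1L), cbind(neg, label = -1L))
    benchmark <- benchmark[sample.int(nrow(benchmark)), ]
    rownames(benchmark) <- NULL

    structure(list(triplets = triplets, truth_flags = truth_flags,
                   benchmark_pairs = benchmark, blocks = block_of,
                   config = config),
              class = "synth_output")
  })
}

#' @export
print.synth_output <- function(x, ...) {
  cat(sprintf("synth_output: %d triplets (%d spurious), %d benchmark pairs\n",
              nrow(x$triplets), sum(!x$truth_flags),
              nrow(x$benchmark_pairs)))
  invisible(x)
}

#' Derive a labelled polypharmacy benchmark from a synthetic graph
#'
#' Valid triples pair same-block drugs with a side effect assigned to
#' their block; invalid triples are sampled from the complement (see
#' [sample_negative_triples()]). Side-effect vertices are new identifiers
#' (`SE...`), appended as extra triplet records linking them to their
#' block's drugs so they receive embeddings.
#'
#' @param output A `synth_output`.
#' @param n_side_effects Side-effect vocabulary size.
#' @param n_valid Number of valid (label 1) triples to sample.
#' @param seed Integer seed.
#' @return List with `triples` (balanced labelled triples), `records`
#'   (extra triplet records for the side-effect vertices).
#' @export
synth_polypharmacy <- function(output, n_side_effects = 10L, n_valid = 100L,
                               seed = 1L) {
  stopifnot(inherits(output, "synth_output"))
  cfg <- output$config
  drugs <- sprintf("DRUG%03d", seq_len(cfg$n_drugs))
  ses <- sprintf("SE%03d", seq_len(n_side_effects))
  se_block <- rep_len(seq_len(cfg$n_blocks), n_side_effects)
  block_of <- output$blocks
  with_seed(seed, {
    cand <- expand.grid(drug1 = drugs, drug2 = drugs,
                        stringsAsFactors = FALSE)
    cand <- cand[cand$drug1 < cand$drug2, ]
    same <- block_of[cand$drug1] == block_of[cand$drug2]
    cand <- cand[same, ]
    rows <- cand[sample.int(nrow(cand), n_valid, replace = TRUE), ]
    se_pick <- vapply(block_of[rows$drug1], function(b) {
      pool <- ses[se_block == b]
      pool[sample.int(length(pool), 1L)]
    }, "")
    valid <- unique(data.frame(drug1 = rows$drug1, side_effect = se_pick,
                               drug2 = rows$drug2, label = 1L,
                               stringsAsFactors = FALSE))
    invalid <- sample_negative_triples(valid, nrow(valid), drugs, ses,
                                       seed = seed + 1L)
    records <- triples_to_records(valid[c("drug1", "side_effect", "drug2")])
    list(triples = rbind(valid, invalid), records = records)
  })
}

#' Export a synthetic knowledge graph to disk
#'
#' Writes the triplet TSV (readable by [read_triplets()]), the benchmark
#' pair CSV, and a truth-flag sidecar (`truth_flags.tsv`) that is for test
#' inspection only and never consumed by the pipeline.
#'
#' @param output A `synth_output`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written.
#' @export
export_synth_kg <- function(output, dir) {
  stopifnot(inherits(output, "synth_output"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f_trip <- file.path(dir, "triplets.tsv")
  f_pairs <- file.path(dir, "benchmark_pairs.csv")
  f_truth <- file.path(dir, "truth_flags.tsv")
  tri <- output$triplets
  header <- paste(c("SUBJECT_ID", "PREDICATE", "OBJECT_ID", "SUBJECT_SCORE",
                    "OBJECT_SCORE", "COOCCURRENCE"), collapse = "\t")
  body <- paste(tri$subject_id, tri$predicate, tri$object_id,
                formatC(tri$subject_score, digits = 10, format = "g"),
                formatC(tri$object_score, digits = 10, format = "g"),
                format(tri$cooccurrence, scientific = FALSE, trim = TRUE),
                sep = "\t")
  writeLines(c(header, body), f_trip)
  pairs <- output$benchmark_pairs
  utils::write.csv(data.frame(DRUG_ID = pairs$drug_id,
                              DISEASE_ID = pairs$disease_id,
                              LABEL = pairs$label),
                   f_pairs, row.names = FALSE, quote = FALSE)
  writeLines(c("TRUTH", as.character(as.integer(output$truth_flags))),
             f_truth)
  c(triplets = f_trip, benchmark_pairs = f_pairs, truth_flags = f_truth)
}
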